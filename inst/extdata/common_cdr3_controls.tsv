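sequence	chain	n_samples	total_count	fraction
ARTSGAKYWPNNPDY	IGH	1	776	2.90
AKDSDSSSRYSSSWYPAYNFDY	IGH	2	5071	2.64
AREPVHYGTYYAWGNFDY	IGH	1	460	2.32
QQSLHFPPT	IGK	25	5873	22.89
QQSLHLPPT	IGK	13	3598	14.26
GQGIQYPFT	IGK	12	1425	5.03
STWDDSLSAPV	IGL	27	1612	4.12
SSDDDSLSSVV	IGL	16	9498	3.58
STWDDSLSAAV	IGL	39	2107	2.30
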