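genome_id	class	hgt	total
B. meristosporus CBS 931.73	Total	26	44
B. meristosporus CBS 931.73	NRPS/NRPS-like	22	30
B. meristosporus CBS 931.73	PKS/PKS-like	2	4
B. meristosporus CBS 931.73	NRPS-PKS hybrids	0	0
B. meristosporus CBS 931.73	TC	2	10
B. meristosporus B9252	Total	12	44
B. meristosporus B9252	NRPS/NRPS-like	9	30
B. meristosporus B9252	PKS/PKS-like	1	7
B. meristosporus B9252	NRPS-PKS hybrids	0	1
B. meristosporus B9252	TC	2	6
B. heterosporus B8920	Total	7	23
B. heterosporus B8920	NRPS/NRPS-like	7	18
B. heterosporus B8920	PKS/PKS-like	0	1
B. heterosporus B8920	NRPS-PKS hybrids	0	0
B. heterosporus B8920	TC	0	4
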