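feature	pos	token	weight
intercept	NA	NA	0.6
gc_low	NA	NA	-0.2
gc_high	NA	NA	-0.17
nt	25	T	0.336817603
nt	3	T	-0.425829299
nt	6	C	-0.40090429
nt	4	A	0.075313102
nt	9	A	-0.15066319
nt	6	A	0.015546154
nt	7	T	0.394679461
nt	17	T	0.075852434
nt	16	C	0.206883158
nt	21	G	-0.271397669
nt	10	G	0.014467382
nt	19	C	0.106905805
nt	27	G	0.011692867
nt	9	C	-0.475234258
nt	19	G	0.346838698
nt	17	C	-0.028419873
nt	12	G	0.128440128
nt	10	T	0.31186338
nt	28	A	0.121575947
nt	23	T	-0.072722796
nt	11	A	0.042180114
nt	15	T	0.304948185
nt	25	A	-0.101339661
nt	8	T	-0.293040326
nt	3	A	0.074065376
nt	9	T	0.212057564
nt	7	A	-0.085584805
nt	30	G	0.040705572
nt	6	G	0.152307856
nt	23	A	-0.104952811
nt	14	A	-0.202751219
nt	22	G	0.105670829
nt	14	T	-0.204447081
nt	18	C	0.085405314
nt	18	G	-0.178826821
nt	19	T	-0.227258891
nt	13	T	-0.161810148
nt	2	C	0.205853671
dinucleotide	25	AT	-0.186126982
dinucleotide	23	CC	0.065852464
dinucleotide	4	GC	-0.034073064
dinucleotide	19	GA	0.081497139
dinucleotide	17	AG	0.072463141
dinucleotide	19	CC	-0.067423508
dinucleotide	10	CT	0.063565404
dinucleotide	10	CG	-0.12404666
dinucleotide	9	TG	-0.003862279
dinucleotide	17	CG	-0.06370882
dinucleotide	23	CA	-0.045346702
dinucleotide	23	AT	-0.142271364
dinucleotide	26	TG	-0.01070497
dinucleotide	22	AT	-0.097675452
dinucleotide	14	AA	-0.050812157
dinucleotide	19	AA	0.091271364
dinucleotide	20	CC	0.115313355
dinucleotide	15	GC	-0.104181935
dinucleotide	14	GC	-0.24293413
dinucleotide	14	CT	-0.135757525
dinucleotide	20	TG	0.081316885
dinucleotide	26	AG	-0.040977082
dinucleotide	19	AC	-0.04738904
dinucleotide	10	GT	0.145737381
dinucleotide	20	GC	-0.01313705
dinucleotide	8	AT	-0.227821954
dinucleotide	19	CG	-0.10781182
dinucleotide	6	AT	-0.214000638
dinucleotide	16	GT	-0.109340499
dinucleotide	23	GT	-0.110070974
dinucleotide	13	CA	-0.007410556
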