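# Cholinesterase inhibition of the 25 isolated compounds (0.1 mg/mL),
# mean +/- SEM of >= 3 replicates.  ND = not detected.
agent_id	enzyme	mean_inhibition	sem	n	role
1	AChE	17.9	0.3	3	compound
2	AChE	15.2	0.2	3	compound
3	AChE	12.5	0.4	3	compound
4	AChE	ND	ND	3	compound
5	AChE	14.1	0.3	3	compound
6	AChE	17.9	0.2	3	compound
7	AChE	14.2	0.5	3	compound
8	AChE	ND	ND	3	compound
9	AChE	ND	ND	3	compound
10	AChE	0.9	0.1	3	compound
11	AChE	7.9	0.3	3	compound
12	AChE	1.7	0.2	3	compound
13	AChE	18.5	0.4	3	compound
14	AChE	27.2	0.2	3	compound
15	AChE	21.6	0.4	3	compound
16	AChE	1.1	0.1	3	compound
17	AChE	13.2	0.3	3	compound
18	AChE	15.9	0.4	3	compound
19	AChE	23.5	0.4	3	compound
20	AChE	18.4	0.4	3	compound
21	AChE	19.2	0.3	3	compound
22	AChE	17.3	0.3	3	compound
23	AChE	20.3	0.5	3	compound
24	AChE	21.1	0.6	3	compound
25	AChE	22.4	0.2	3	compound
1	BuChE	37.6	0.6	3	compound
2	BuChE	28.1	0.4	3	compound
3	BuChE	75.8	0.7	3	compound
4	BuChE	ND	ND	3	compound
5	BuChE	35.3	0.5	3	compound
6	BuChE	36.0	0.4	3	compound
7	BuChE	0.6	0.1	3	compound
8	BuChE	ND	ND	3	compound
9	BuChE	ND	ND	3	compound
10	BuChE	0.1	0.1	3	compound
11	BuChE	4.0	0.2	3	compound
12	BuChE	15.1	0.3	3	compound
13	BuChE	0.5	0.1	3	compound
14	BuChE	4.2	0.2	3	compound
15	BuChE	ND	ND	3	compound
16	BuChE	ND	ND	3	compound
17	BuChE	ND	ND	3	compound
18	BuChE	ND	ND	3	compound
19	BuChE	12.3	0.6	3	compound
20	BuChE	ND	ND	3	compound
21	BuChE	ND	ND	3	compound
22	BuChE	ND	ND	3	compound
23	BuChE	7.3	0.2	3	compound
24	BuChE	ND	ND	3	compound
25	BuChE	2.8	0.2	3	compound
Donepezil	AChE	98.2	0.8	3	positive-control
Donepezil	BuChE	79.8	0.7	3	positive-control
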