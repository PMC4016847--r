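# Cholinesterase inhibition of crude rhizome extracts (1 mg/mL), mean +/- SEM
# of >= 3 replicates.  ND = not detected.  Donepezil is the positive control.
agent_id	technique	enzyme	mean_inhibition	sem	n	role
Petroleum ether	ultrasonic	AChE	ND	ND	3	extract
Dichloromethane	ultrasonic	AChE	ND	ND	3	extract
Ethyl acetate	ultrasonic	AChE	ND	ND	3	extract
Acetone	ultrasonic	AChE	ND	ND	3	extract
Methanol	ultrasonic	AChE	ND	ND	3	extract
95% ethanol	ultrasonic	AChE	ND	ND	3	extract
70% ethanol	ultrasonic	AChE	ND	ND	3	extract
50% ethanol	ultrasonic	AChE	ND	ND	3	extract
30% ethanol	ultrasonic	AChE	ND	ND	3	extract
Water	ultrasonic	AChE	ND	ND	3	extract
Petroleum ether	heat-reflux	AChE	ND	ND	3	extract
Dichloromethane	heat-reflux	AChE	ND	ND	3	extract
Ethyl acetate	heat-reflux	AChE	ND	ND	3	extract
Acetone	heat-reflux	AChE	ND	ND	3	extract
Methanol	heat-reflux	AChE	ND	ND	3	extract
95% ethanol	heat-reflux	AChE	ND	ND	3	extract
70% ethanol	heat-reflux	AChE	ND	ND	3	extract
50% ethanol	heat-reflux	AChE	ND	ND	3	extract
30% ethanol	heat-reflux	AChE	ND	ND	3	extract
Water	heat-reflux	AChE	ND	ND	3	extract
Petroleum ether	cold-soak	AChE	ND	ND	3	extract
Dichloromethane	cold-soak	AChE	ND	ND	3	extract
Ethyl acetate	cold-soak	AChE	ND	ND	3	extract
Acetone	cold-soak	AChE	ND	ND	3	extract
Methanol	cold-soak	AChE	ND	ND	3	extract
95% ethanol	cold-soak	AChE	ND	ND	3	extract
70% ethanol	cold-soak	AChE	ND	ND	3	extract
50% ethanol	cold-soak	AChE	ND	ND	3	extract
30% ethanol	cold-soak	AChE	ND	ND	3	extract
Water	cold-soak	AChE	ND	ND	3	extract
Petroleum ether	ultrasonic	BuChE	ND	ND	3	extract
Dichloromethane	ultrasonic	BuChE	41.5	0.5	3	extract
Ethyl acetate	ultrasonic	BuChE	44.1	0.5	3	extract
Acetone	ultrasonic	BuChE	38.8	0.3	3	extract
Methanol	ultrasonic	BuChE	12.3	0.4	3	extract
95% ethanol	ultrasonic	BuChE	4.9	0.2	3	extract
70% ethanol	ultrasonic	BuChE	1.8	0.1	3	extract
50% ethanol	ultrasonic	BuChE	2.8	0.1	3	extract
30% ethanol	ultrasonic	BuChE	2.4	0.1	3	extract
Water	ultrasonic	BuChE	ND	ND	3	extract
Petroleum ether	heat-reflux	BuChE	ND	ND	3	extract
Dichloromethane	heat-reflux	BuChE	15.7	0.7	3	extract
Ethyl acetate	heat-reflux	BuChE	27.7	0.4	3	extract
Acetone	heat-reflux	BuChE	22.2	0.3	3	extract
Methanol	heat-reflux	BuChE	5.4	0.2	3	extract
95% ethanol	heat-reflux	BuChE	2.8	0.1	3	extract
70% ethanol	heat-reflux	BuChE	ND	ND	3	extract
50% ethanol	heat-reflux	BuChE	ND	ND	3	extract
30% ethanol	heat-reflux	BuChE	ND	ND	3	extract
Water	heat-reflux	BuChE	ND	ND	3	extract
Petroleum ether	cold-soak	BuChE	1.6	0.1	3	extract
Dichloromethane	cold-soak	BuChE	41.2	0.6	3	extract
Ethyl acetate	cold-soak	BuChE	40.8	0.8	3	extract
Acetone	cold-soak	BuChE	37.9	0.7	3	extract
Methanol	cold-soak	BuChE	7.1	0.3	3	extract
95% ethanol	cold-soak	BuChE	3.9	0.3	3	extract
70% ethanol	cold-soak	BuChE	1.6	0.2	3	extract
50% ethanol	cold-soak	BuChE	0.5	0.1	3	extract
30% ethanol	cold-soak	BuChE	1.8	0.2	3	extract
Water	cold-soak	BuChE	ND	ND	3	extract
Donepezil	reference	AChE	98.0	0.5	3	positive-control
Donepezil	reference	BuChE	80.2	0.6	3	positive-control
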