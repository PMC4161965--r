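Pathway	Weighted_KS	L2Norm	Mean	WeightedSigRatio	SigRatio	GeometricMean	FisherMethod	RankSum
REACTOME DNA STRAND ELONGATION	0	5	4	2	4	1	1	2
REACTOME ACTIVATION OF THE PRE REPLICATIVE COMPLEX	2	9	2	4	6	3	3	19
PID FOXM1PATHWAY	1	2	3	10	20	5	4	5
PID AURORA B PATHWAY	3	4	11	1	13	4	5	25
REACTOME G1 S SPECIFIC TRANSCRIPTION	9	7	1	18	12	2	2	16
REACTOME G1 PHASE	11	6	8	15	21	8	7	4
PID ATR PATHWAY	0	19	14	3	5	9	11	13
KEGG DNA REPLICATION	8	16	10	5	8	11	10	18
REACTOME G2 M CHECKPOINTS	18	8	5	25	1	13	9	7
REACTOME CYCLIN A B1 ASSOCIATED EVENTS DURING G2 M TRANSITION	10	1	12	16	0	6	6	29
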