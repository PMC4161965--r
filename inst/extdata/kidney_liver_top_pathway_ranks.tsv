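Pathway	Weighted_KS	L2Norm	Mean	WeightedSigRatio	SigRatio	GeometricMean	FisherMethod	RankSum
BIOCARTA AMI PATHWAY	1	2	7	1	15	1	1	2
REACTOME XENOBIOTICS	3	1	6	3	23	2	2	1
REACTOME COMPLEMENT CASCADE	0	4	9	0	6	4	9	4
BIOCARTA INTRINSIC PATHWAY	2	3	8	2	26	3	3	3
BIOCARTA COMP PATHWAY	0	10	1	0	0	8	6	8
KEGG PRIMARY BILE ACID BIOSYNTHESIS	4	6	12	0	0	10	8	7
KEGG RETINOL METABOLISM	11	8	13	0	0	6	4	6
KEGG COMPLEMENT AND COAGULATION CASCADES	12	11	10	0	0	9	7	5
REACTOME BILE ACID AND BILE SALT METABOLISM	0	9	11	0	10	5	10	9
REACTOME SYNTHESIS OF BILE ACIDS AND BILE SALTS	9	5	14	0	18	7	5	15
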