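genome	gene	strand	start	end	size	start_codon	stop_codon
Trichogramma_japonicum	trnW	-	1	66	66
Trichogramma_japonicum	nad2	-	67	1078	1014	ATA	TA
Trichogramma_japonicum	trnQ	-	1079	1146	68
Trichogramma_japonicum	trnY	-	1164	1230	67
Trichogramma_japonicum	cox1	-	1272	2807	1536	ATG	TAA
Trichogramma_japonicum	trnE	+	2823	2889	67
Trichogramma_japonicum	trnF	-	2915	2978	64
Trichogramma_japonicum	trnI	-	2985	3051	67
Trichogramma_japonicum	trnS1	-	3055	3113	59
Trichogramma_japonicum	trnN	-	3181	3246	66
Trichogramma_japonicum	trnC	-	3267	3335	69
Trichogramma_japonicum	cox3	-	3388	4179	792	ATG	TAA
Trichogramma_japonicum	atp6	-	4215	4889	675	ATG	TAA
Trichogramma_japonicum	atp8	-	4883	5050	168	ATT	TAA
Trichogramma_japonicum	trnD	-	5132	5197	66
Trichogramma_japonicum	trnK	+	5210	5279	70
Trichogramma_japonicum	cox2	-	5294	5974	681	ATT	TAA
Trichogramma_japonicum	trnL2	-	5975	6040	66
Trichogramma_japonicum	nad5	-	6072	7757	1686	ATA	TAA
Trichogramma_japonicum	trnH	-	7759	7825	67
Trichogramma_japonicum	nad4	-	7847	9190	1344	ATG	TAA
Trichogramma_japonicum	nad4l	-	9184	9471	288	ATT	TAA
Trichogramma_japonicum	trnT	+	9482	9546	65
Trichogramma_japonicum	trnP	-	9546	9611	66
Trichogramma_japonicum	nad6	+	9618	10196	579	ATT	TAA
Trichogramma_japonicum	cob	+	10230	11369	1140	ATG	TAA
Trichogramma_japonicum	trnS2	+	11395	11458	64
Trichogramma_japonicum	nad1	-	11457	12392	936	ATT	TAA
Trichogramma_japonicum	trnL1	-	12393	12457	65
Trichogramma_japonicum	rrnL	-	12458	13857	1400
Trichogramma_japonicum	trnA	-	13858	13922	65
Trichogramma_japonicum	trnG	-	13937	14001	65
Trichogramma_japonicum	rrnS	-	14002	14791	790
Trichogramma_japonicum	trnV	-	14792	14857	66
Trichogramma_japonicum	trnR	-	14856	14920	65
Trichogramma_japonicum	nad3	-	14939	15301	363	ATA	TAA
Trichogramma_japonicum	trnM	-	15302	15369	68
Trichogramma_japonicum	CR	+	15370	15962	593
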