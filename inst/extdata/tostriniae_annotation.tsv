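genome	gene	strand	start	end	size	start_codon	stop_codon
Trichogramma_ostriniae	trnW	-	1	67	67
Trichogramma_ostriniae	nad2	-	68	1080	1014	ATA	T
Trichogramma_ostriniae	trnQ	-	1081	1148	68
Trichogramma_ostriniae	trnY	-	1212	1277	66
Trichogramma_ostriniae	cox1	-	1340	2875	1536	ATG	TAA
Trichogramma_ostriniae	trnE	+	2877	2942	66
Trichogramma_ostriniae	trnF	-	2945	3009	65
Trichogramma_ostriniae	trnI	-	3181	3247	67
Trichogramma_ostriniae	trnS1	-	3248	3307	60
Trichogramma_ostriniae	trnN	-	3459	3524	66
Trichogramma_ostriniae	trnC	-	3525	3592	68
Trichogramma_ostriniae	cox3	-	3699	4490	792	ATG	TAA
Trichogramma_ostriniae	atp6	-	4515	5189	675	ATG	TAA
Trichogramma_ostriniae	atp8	-	5183	5350	168	ATT	TAA
Trichogramma_ostriniae	trnD	-	5423	5488	66
Trichogramma_ostriniae	trnK	+	5496	5565	70
Trichogramma_ostriniae	cox2	-	5575	6255	681	ATT	TAA
Trichogramma_ostriniae	trnL2	-	6256	6321	66
Trichogramma_ostriniae	nad5	-	6351	8033	1683	ATT	TAA
Trichogramma_ostriniae	trnH	-	8040	8102	63
Trichogramma_ostriniae	nad4	-	8133	9476	1344	ATG	TAA
Trichogramma_ostriniae	nad4l	-	9470	9757	288	ATT	TAG
Trichogramma_ostriniae	trnT	+	9758	9821	64
Trichogramma_ostriniae	trnP	-	9821	9885	65
Trichogramma_ostriniae	nad6	+	9899	10471	573	ATG	TAA
Trichogramma_ostriniae	cob	+	10474	11613	1140	ATG	TAA
Trichogramma_ostriniae	trnS2	+	11633	11696	64
Trichogramma_ostriniae	nad1	-	11695	12630	936	ATT	TAA
Trichogramma_ostriniae	trnL1	-	12631	12700	70
Trichogramma_ostriniae	rrnL	-	12701	14067	1367
Trichogramma_ostriniae	trnA	-	14068	14131	64
Trichogramma_ostriniae	trnG	-	14142	14208	67
Trichogramma_ostriniae	rrnS	-	14209	14983	775
Trichogramma_ostriniae	trnV	-	14984	15051	68
Trichogramma_ostriniae	trnR	-	15051	15113	63
Trichogramma_ostriniae	nad3	-	15217	15576	360	ATA	TAA
Trichogramma_ostriniae	trnM	-	15577	15642	66
Trichogramma_ostriniae	CR	+	15643	16472	830
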