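gene	start	end	strand	length	start_codon	stop_codon	anticodon
trnF	1	68	+	68			gaa
rrnS	69	1051	+	983
trnV	1052	1121	+	70			uac
rrnL	1122	2723	+	1602
trnL2	2724	2798	+	75			uaa
ND1	2804	3781	+	978	ATG	AGA
trnI	3794	3865	+	72			gau
trnQ	3873	3943	-	71			uug
trnM	3943	4011	+	69			cau
ND2	4012	5051	+	1040	GTG	TA
trnW	5052	5122	+	71			uca
trnA	5124	5192	-	69			ugc
trnN	5197	5269	-	73			guu
trnC	5270	5336	-	67			gca
trnY	5336	5406	-	71			gua
COX1	5408	6958	+	1551	GTG	AGG
trnS2	6950	7024	-	75			uga
trnD	7028	7096	+	69			guc
COX2	7104	7787	+	684	ATG	TAA
trnK	7789	7856	+	68			uuu
ATP8	7858	8025	+	168	ATG	TAA
ATP6	8016	8699	+	684	ATG	TAA
COX3	8705	9488	+	784	ATG	T
trnG	9489	9557	+	69			ucc
ND3	9558	9908	+	351	ATG	TAA
trnR	9910	9979	+	70			ucg
ND4L	9981	10277	+	297	ATG	TAA
ND4	10271	11648	+	1378	ATG	T
trnH	11649	11719	+	71			gug
trnS1	11722	11786	+	65			gcu
trnL1	11786	11856	+	71			uag
ND5	11857	13674	+	1818	ATG	AGA
Cytb	13683	14825	+	1143	ATG	TAA
trnT	14829	14897	+	69			ugu
trnP	14904	14973	-	70			ugg
ND6	14990	15508	-	519	ATG	AGG
trnE	15510	15581	-	72			uuc
D-loop	15582	16803	+	1222
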