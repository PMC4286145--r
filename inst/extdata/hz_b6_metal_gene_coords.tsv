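HALZIN_54	JNCK01000001.1	48442	49500	+	RND family efflux transporter, MFP subunit
HALZIN_399	JNCK01000001.1	433553	434005	+	MerR family Cd(II)/Pb(II)-responsive transcriptional regulator
HALZIN_733	JNCK01000001.1	778272	780812	+	Heavy metal translocating P-type ATPase ZntA
HALZIN_916	JNCK01000001.1	977118	976882	-	Mercuric transport protein MerE
HALZIN_917	JNCK01000001.1	977480	977115	-	Transcriptional regulator MerD
HALZIN_918	JNCK01000001.1	978239	977592	-	Alkylmercury lyase MerB
HALZIN_919	JNCK01000001.1	979028	978390	-	Alkylmercury lyase MerB
HALZIN_920	JNCK01000001.1	979808	979179	-	Alkylmercury lyase MerB
HALZIN_922	JNCK01000001.1	980118	980540	+	Transcriptional regulator MerR
HALZIN_934	JNCK01000001.1	994405	993521	-	Magnesium and cobalt efflux protein CorC
HALZIN_1240	JNCK01000001.1	1334217	1331998	-	Heavy metal translocating P-type ATPase
HALZIN_1392	JNCK01000001.1	1499237	1498659	-	Superoxide dismutase
HALZIN_1411	JNCK01000001.1	1521826	1522995	+	RND family efflux transporter, MFP subunit
HALZIN_1413	JNCK01000001.1	1526330	1526785	+	Zinc uptake regulation protein ZUR
HALZIN_2047	JNCK01000001.1	2179598	2182789	+	RND family efflux transporter protein
HALZIN_2196	JNCK01000001.1	2338252	2335574	-	Heavy metal translocating P-type ATPase ZntA
HALZIN_2208	JNCK01000001.1	2355137	2351976	-	RND family efflux transporter protein
HALZIN_2209	JNCK01000001.1	2356423	2351976	-	RND family efflux transporter, MFP subunit
HALZIN_2260	JNCK01000001.1	2411989	2410787	-	Multicopper oxidase
HALZIN_2261	JNCK01000001.1	2412630	2413034	+	Transcriptional regulator MerR
HALZIN_2262	JNCK01000001.1	2413107	2415596	+	Heavy metal translocating P-type ATPase
HALZIN_2264	JNCK01000001.1	2416527	2416976	+	Transcriptional regulator MerR
HALZIN_2268	JNCK01000001.1	2423176	2423622	+	CopG family transcriptional regulator
HALZIN_2271	JNCK01000001.1	2424931	2425086	+	Copper resistance protein CopC
HALZIN_2272	JNCK01000001.1	2425115	2425978	+	Copper resistance protein CopD
HALZIN_2469	JNCK01000001.1	2658088	2657690	-	Transcriptional regulator MerR
HALZIN_2470	JNCK01000001.1	2658244	2658588	+	Mercuric transport protein MerT
HALZIN_2471	JNCK01000001.1	2658620	2658925	+	Periplasmic mercury(+2) binding protein MerP
HALZIN_2472	JNCK01000001.1	2658988	2660622	+	Mercuric reductase, MerA family
HALZIN_2675	JNCK01000001.1	2872087	2872584	+	Transcriptional regulator MerR
HALZIN_3265	JNCK01000001.1	3489632	3489021	-	Superoxide dismutase
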