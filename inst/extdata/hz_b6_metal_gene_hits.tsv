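gene_id	organism	class	identity	accession
HALZIN_54	Idiomarina sediminum	Gammaproteobacteria	44%	WP_026860724
HALZIN_399	Halomonas lutea	Gammaproteobacteria	75%	WP_019019418
HALZIN_733	Gracilimonas tropica	Sphingobacteriia	59%	WP_020403952
HALZIN_916	Burkholderia cepacia	Betaproteobacteria	99%	YP_006965885
HALZIN_917	Pseudomonas putida	Gammaproteobacteria	98%	WP_012806008
HALZIN_918	Paraglaciecola polaris	Gammaproteobacteria	84%	WP_007106069
HALZIN_919	Paraglaciecola polaris	Gammaproteobacteria	94%	WP_007106069
HALZIN_920	Paraglaciecola polaris	Gammaproteobacteria	90%	WP_007106069
HALZIN_922	Stenotrophomonas maltophilia	Gammaproteobacteria	99%	WP_005413398
HALZIN_934	Chromohalobacter salexigens	Gammaproteobacteria	81%	WP_011507633
HALZIN_1240	Halomonas sp.	Gammaproteobacteria	97%	WP_023004666
HALZIN_1392	Halomonas smyrnensis	Gammaproteobacteria	85%	WP_016854901
HALZIN_1411	Halomonas lutea	Gammaproteobacteria	76%	WP_019017686
HALZIN_1413	Halomonas lutea	Gammaproteobacteria	82%	WP_019017691
HALZIN_2047	Pseudoxanthomonas suwonensis	Gammaproteobacteria	85%	WP_013535339
HALZIN_2196	Halomonas lutea	Gammaproteobacteria	65%	WP_019020337
HALZIN_2208	Pseudomonas alcaligenes	Gammaproteobacteria	58%	WP_021217164
HALZIN_2209	Halomonas lutea	Gammaproteobacteria	53%	WP_019020155
HALZIN_2260	Sphingopyxis baekryungensis	Alphaproteobacteria	55%	WP_022673021
HALZIN_2261	Halomonas lutea	Gammaproteobacteria	90%	WP_019017365
HALZIN_2262	Halomonas lutea	Gammaproteobacteria	92%	WP_019017357
HALZIN_2264	Halomonas lutea	Gammaproteobacteria	89%	WP_026300314
HALZIN_2268	Halomonas lutea	Gammaproteobacteria	80%	WP_019017364
HALZIN_2271	Hyphomonas neptunium	Alphaproteobacteria	51%	WP_011646711
HALZIN_2272	Thialkalivibrio sp.	Gammaproteobacteria	43%	WP_018881395
HALZIN_2469	Halomonas lutea	Gammaproteobacteria	90%	WP_019020805
HALZIN_2470	Halomonas lutea	Gammaproteobacteria	78%	WP_019020806
HALZIN_2471	Halomonas lutea	Gammaproteobacteria	82%	WP_019020807
HALZIN_2472	Halomonas lutea	Gammaproteobacteria	93%	WP_019020808
HALZIN_2675	Halomonas sp.	Gammaproteobacteria	66%	WP_023005510
HALZIN_3265	Halomonas lutea	Gammaproteobacteria	74%	WP_019019731
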