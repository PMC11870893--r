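disease	material	support_pct	confidence_pct	lift
Wound	Rumex abyssinicus Jacq.	1.39	17.95	5.33
Wound	Conyza steudelii Sch.-Bip. ex A. Rich.	1.19	15.38	5.55
Wound	Plumbago zeylanica L.	0.99	12.82	2.02
Wound	Calpurnia aurea (Ait.) Benth.	0.79	10.26	2.35
Mental illness	Clerodendrum myricoides (Hochst.) R. Br. ex Vatke	1.58	29.63	3.48
Mental illness	Ruta chalepensis L.	1.19	22.22	3.87
Mental illness	Clausena anisata (Willd.) Benth.	0.79	14.81	4.68
Mental illness	Trigonella foenum-graecum L.	0.59	11.11	7.01
Mental illness	Cannabis sativa L.	0.59	11.11	5.10
Mental illness	Withania somnifera (L.) Dunal	0.59	11.11	2.81
Mental illness	Gladiolus psittacinus Hook.	0.59	11.11	3.74
Mental illness	Verbena officinalis L.	0.59	11.11	2.95
Mental illness	Lepidium sativum L.	0.59	11.11	2.95
Mental illness	Asparagus africanus Lam.	0.59	11.11	2.44
Mental illness	Securidaca longepedunculata Fresen.	0.59	11.11	2.44
Mental illness	Capparis tomentosa Lam.	0.59	11.11	2.67
Mental illness	Adhatoda schimperiana (Hochst) Nees.	0.59	11.11	2.34
Mental illness	Myrrh (Commiphora cf. crenulata or other C. spp.)	0.59	11.11	2.08
Mental illness	Cucumis ficifolius A. Rich.	0.59	11.11	1.22
Sexual stimulation (aphrodisiacs)	Tragia pungens (Forssk.) Muell. Arg.	1.19	33.33	28.06
Sexual stimulation (aphrodisiacs)	Asparagus africanus Lam.	0.99	27.78	23.38
Sexual stimulation (aphrodisiacs)	Ferula communis L.	0.99	27.78	9.35
Sexual stimulation (aphrodisiacs)	Thalictrum rhynchocarpum Dill. & A. Rich.	0.79	22.22	4.32
Sexual stimulation (aphrodisiacs)	Phoenix reclinata Jacq.	0.59	16.67	7.65
Sexual stimulation (aphrodisiacs)	Sida cuneifolia Roxb.	0.59	16.67	7.01
Sexual stimulation (aphrodisiacs)	Olea europaea L. subsp. africana (Mill.) P.S. Green	0.59	16.67	6.47
Sexual stimulation (aphrodisiacs)	Gladiolus psittacinus Hook.	0.59	16.67	5.61
Sexual stimulation (aphrodisiacs)	Cucumis ficifolius A. Rich.	0.59	16.67	1.83
Sexual stimulation (aphrodisiacs)	Habenaria sp.	0.40	11.11	28.06
Sexual stimulation (aphrodisiacs)	Sida cuneifolia Roxb. or S. ovata Forssk.	0.40	11.11	9.35
Sexual stimulation (aphrodisiacs)	Tragia pungens (Forssk) Muell. Arg.	0.40	11.11	8.02
Sexual stimulation (aphrodisiacs)	Catha edulis (Vahl) Forssk. ex Endl.	0.40	11.11	9.35
Sexual stimulation (aphrodisiacs)	Stylochiton kerensis N.E. Brown	0.40	11.11	6.23
Sexual stimulation (aphrodisiacs)	Cannabis sativa L.	0.40	11.11	5.10
Sexual stimulation (aphrodisiacs)	Zehneria scabra (L.f.) Sonder	0.40	11.11	2.67
Sexual stimulation (aphrodisiacs)	Clerodendrum myricoides (Hochst.) R. Br. ex Vatke	0.40	11.11	1.30
Eye disease	Hagenia abyssinica (Bruce) J.F. Gmel.	0.59	18.75	7.28
Eye disease	Premna schimperi Engl.	0.40	12.50	9.02
Eye disease	Artemisia afra Jacq. ex Willd.	0.40	12.50	7.89
Eye disease	Vitis vinifera L.	0.40	12.50	5.74
Eye disease	Solanum marginatum L.f.	0.40	12.50	5.26
Rabies	Cucumis ficifolius A. Rich.	1.39	43.75	4.80
Rabies	Phytolacca dodecandra L'Herit.	0.99	31.25	10.52
Rabies	Cyphostemma junceum (Webb) Descoings ex Wild & Drummond	0.79	25.00	10.52
Rabies	Solanum cf. adoense Hochst.	0.79	25.00	4.86
Rabies	Adhatoda schimperiana (Hochst) Nees.	0.59	18.75	3.95
Rabies	Sida cuneifolia Roxb. or S. ovata Forssk.	0.40	12.50	10.52
Rabies	Senecio myriocephalus Sch. Bip. ex A.Rich.	0.40	12.50	7.01
Rabies	Vitis vinifera L.	0.40	12.50	5.74
Rabies	Kalanchoe petitiana A. Rich.	0.40	12.50	5.74
Rabies	Mandragora officinarum/Luffa aegyptica	0.40	12.50	4.86
Frequent miscarriage	Osyris quadripartita Decne.	0.59	18.75	5.57
Frequent miscarriage	Clutia abyssinica Jaub. & Spach.	0.59	18.75	6.31
Frequent miscarriage	Solanum cf. adoense Hochst.	0.59	18.75	3.64
Frequent miscarriage	Cucumis ficifolius A. Rich.	0.59	18.75	2.06
Frequent miscarriage	Periploca linearifolia A. Rich. & Quart.-Dill.	0.40	12.50	10.52
Frequent miscarriage	Aloe sp.	0.40	12.50	6.31
Frequent miscarriage	Rumex nervosus Vahl	0.40	12.50	4.86
Leprosy	Plumbago zeylanica L.	0.99	33.33	5.26
Leprosy	Withania somnifera (L.) Dunal	0.59	20.00	5.05
Leprosy	Euclea schimperi (DC.) Dandy	0.59	20.00	5.61
Leprosy	Capparis tomentosa Lam.	0.59	20.00	4.81
Leprosy	Sylvicapra grimmia	0.40	13.33	16.83
Leprosy	Maesa lanceolata Forssk.	0.40	13.33	22.44
Leprosy	Ranunculus multifidus Forssk.	0.40	13.33	22.44
Leprosy	Olea europaea L. subsp. africana (Mill.) P.S. Green	0.40	13.33	5.18
Leprosy	Osyris quadripartita Decne.	0.40	13.33	3.96
Leprosy	Clematis simensis Fresen.	0.40	13.33	5.18
Leprosy	Brucea antidysenterica J.F. Mill.	0.40	13.33	3.96
Leprosy	Rumex abyssinicus (Jacq.).	0.40	13.33	3.54
Leprosy	Jasminum floribundum R. Br. ex Fresen.	0.40	13.33	3.06
Leprosy	Acokanthera schimperi (DC.) Oliv.	0.40	13.33	3.21
Leprosy	Cucumis ficifolius A. Rich.	0.40	13.33	1.46
Eczema	Hagenia abyssinica (Bruce) J.F. Gmel.	0.59	21.43	8.32
Eczema	Cucumis ficifolius A. Rich.	0.59	21.43	2.35
Eczema	Lichen	0.40	14.29	14.43
Eczema	Gossypium barbadense L.	0.40	14.29	12.02
Eczema	Mandragora officinarum/Luffa aegyptica	0.40	14.29	5.55
Eczema	Zehneria scabra (L.f.) Sonder	0.40	14.29	3.44
Menorrhagia	Brassica nigra L.	0.59	21.43	12.02
Menorrhagia	Protea gaguedi Gmel.	0.40	14.29	36.07
Menorrhagia	Cordia africana Lam.	0.40	14.29	10.31
Menorrhagia	Nigella sativa L.	0.40	14.29	6.56
Menorrhagia	Achyranthes aspera L.	0.40	14.29	3.61
Menorrhagia	Asparagus africanus Lam.	0.40	14.29	3.14
Malaria	Dodonaea viscosa (L.) Jack.	0.59	25.00	15.78
Malaria	Ekebergia capensis Sparm.	0.40	16.67	12.02
Malaria	Kanahia laniflora (Forssk.) R. Br.	0.40	16.67	7.65
Malaria	Jasminum floribundum R. Br. ex Fresen.	0.40	16.67	3.83
Malaria	Solanum cf. adoens Hochst.	0.40	16.67	3.24
Malaria	Clerodendrum myricoides (Hochst.) R. Br. ex Vatke	0.40	16.67	1.96
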