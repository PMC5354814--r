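class	compound_id	Hs 919.T	RD-ES	SK-ES-1	A673
Camptothecins	Topotecan HCl	< 50	97	96	97
Camptothecins	Irinotecan Hydrochloride	< 50	99	98	83
Alkylating agents	Melphalan	< 50	95	91	< 50
Taxanes	Paclitaxel	< 50	97	96	96
Gold compound	Auranofin	< 50	100	99	98
Estrogen	Estradiol	< 50	< 50	< 50	65
17-alpha-alkylated anabolic steroid	Methyltestosterone	< 50	73	< 50	< 50
Acetanilides; Steroids and Steroid Derivatives	Vorinostat	< 50	61	< 50	< 50
Nitrofurans	Nitrofurazone	< 50	52	72	52
Diphenhydramines	Clemastine	< 50	< 50	< 50	60
Organo-selenium	Ebselen	< 50	95	96	93
Pterins; Keto-Acids	Methotrexate	< 50	82	< 50	89
Amino Acids	Aminopterin	< 50	77	57	85
Carbohydrates	Cytarabine	< 50	93	98	84
Macrocyclic lactone	Rapamycin	< 50	62	51	67
Salicylates and Derivatives	Mycophenolic Acid	< 50	52	< 50	< 50
Benzylisoquinolines	Cycloheximide	< 50	74	81	77
	Tubocurarine chloride	< 50	51	< 50	< 50
	Atractyloside potassium salt	< 50	98	99	99
Thienopyridines	Ticlopidine	< 50	< 50	< 50	66
Electron transport inhibitor	Antimycin A	< 50	69	< 50	< 50
	Pyrvinium pamoate	< 50	98	96	84
Pyridine derivatives	Isoniazid	< 50	< 50	< 50	56
	Trifluridine	< 50	71	< 50	< 50
	Floxuridine	< 50	92	56	68
Purines and purine derivatives	Azathioprine	< 50	< 50	52	< 50
Purines and purine derivatives	Mercaptopurine	< 50	< 50	57	< 50
Purines and purine derivatives	Thioguanosine	< 50	< 50	64	73
Purines and purine derivatives	Clofarabine	< 50	99	98	93
Purines and purine derivatives	Cladribine	< 50	99	89	87
Purines and purine derivatives	Azaguanine-8	< 50	< 50	< 50	83
Purines and purine derivatives	Cyclocytidine	< 50	83	98	86
Benzimidazoles	Albendazole	< 50	93	93	89
Benzimidazoles	Fenbendazole	< 50	86	78	75
Benzimidazoles	Mebendazole	< 50	95	96	94
Benzimidazoles	Flubendazole	< 50	86	86	77
Benzimidazoles	Oxibendazole	< 50	80	84	64
Enzyme inhibitor	Oseltamivir	< 50	95	98	95
Enzyme inhibitor	Disulfiram	< 50	96	95	99
Enzyme inhibitor	Raltitrexed	< 50	80	51	59
Enzyme inhibitor	Novobiocin sodium	< 50	51	< 50	60
Enzyme inhibitor	Amorolfine	< 50	< 50	< 50	56
Camptothecins	Camptothecine	< 50	97	96	99
	AM 404	< 50	< 50	< 50	65
	Etoposide	< 50	84	84	< 50
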