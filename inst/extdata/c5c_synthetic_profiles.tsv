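sample_id	population	region	coverage	variants
Tel_01	Teleut	central_southern_siberia	complete	10454,16093,16518T,16527,16291,8701
Tub_02	Tubalar	central_southern_siberia	complete	10454,16093,16518T,16527,16291,5426
Pol_03	Poles	europe	complete	10454,16093,16518T,16527,16234,7694,1438
Pol_04	Poles	europe	complete	10454,16093,16518T,16527,16234,7694,4769
Pol_05	Poles	europe	complete	10454,16093,16518T,16527,16234,11914
FT_06	FamilyTreeDNA	other	complete	10454,16093,16518T,16527,16234
Alt_07	Altaian	central_southern_siberia	complete	10454,16093,16518T,16527,9545
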