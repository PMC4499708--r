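(Chlamydomonas_reinhardtii:3.0,(Physcomitrella_patens:2.5,(Selaginella_moellendorffii:2.0,((Oryza_sativa:1.0,Zea_mays:1.0)G:1.0,(Solanum_lycopersicum:1.5,(Vitis_vinifera:1.2,(Populus_trichocarpa:1.0,(Glycine_max:0.8,Arabidopsis_thaliana:0.8):0.2)R:0.3):0.3)Eu:0.5)A:0.5)T:0.5)E:0.5)V;
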