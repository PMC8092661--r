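((Ctenophora_NR2A:0.90,(SpNR2_Amphimedon:0.75,(HNF4_Trichoplax:0.55,(HNF4_Nematostella:0.40,HNF4_human:0.40):0.15):0.20):0.15):0.10,((SpNR1_P1:0.60,((SpNR1_P2:0.35,SpNR1_P3:0.35):0.15,SpNR1_P4:0.50):0.10):0.30,((RXR_human:0.45,USP_Drosophila:0.45):0.30,((((COUPTF2_human:0.25,EAR2_human:0.25):0.20,Hydractinia_NR2F:0.45):0.10,(PNR_human:0.40,(TLX_human:0.30,FAX1_Drosophila:0.30):0.10):0.15):0.10,(Trichoplax_21656:0.55,((ER_human:0.35,NR3_Trichoplax:0.35):0.10,((TR_human:0.28,RAR_human:0.28):0.10,(NR4A1_human:0.28,SF1_human:0.28):0.10):0.07):0.10):0.10):0.10):0.15):0.10);
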