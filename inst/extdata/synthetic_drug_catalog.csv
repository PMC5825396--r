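name,pathway_1,ic50_1,pathway_2,ic50_2,pathway_3,ic50_3,pathway_4,ic50_4,pathway_5,ic50_5
syn_ikr_selective,GKr,0.8,,,,,,,,
syn_ical_selective,GCaL,1.2,,,,,,,,
syn_dual_kr_cal,GKr,0.5,GCaL,1.36,,,,,,
syn_triple,GNa,2.0,GKr,1.1,GCaL,3.0,,,,
syn_fivehit,GNa,1.5,GKr,0.9,GCaL,2.4,GKs,4.0,Gto,5.5
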