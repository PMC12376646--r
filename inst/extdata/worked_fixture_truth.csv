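age_group,tissue,timepoint_h,species,g_true,beta_true,x0,x1,x2,labeling_extent_true,comp_synthesis_true,comp_uptake_true
young,liver,24,FFA(16:0),0.315,0,0.7,0.05,0.25,0.29684087684999994,1,0
young,liver,24,FFA(16:1),0.27,0,0.7,0.05,0.25,0.25443503730000006,1,0
young,liver,24,FFA(18:0),0.135,0,0.7,0.05,0.25,0.129552263055,1,0
young,lung,24,FFA(16:0),0.26249999999999996,0.25,0.75,0.05,0.2,0.31043057901474613,0.7609442360735511,0.23905576392644892
young,lung,24,FFA(16:1),0.22499999999999998,0.25,0.75,0.05,0.2,0.2660833534412109,0.760944236073551,0.23905576392644892
young,lung,24,FFA(18:0),0.11249999999999999,0.25,0.75,0.05,0.2,0.13644103855732914,0.7626222571580518,0.2373777428419481
young,cortex,24,FFA(16:0),0.12249999999999998,0.02,0.8099999999999999,0.06,0.13,0.10573732022356497,0.9438531492528132,0.056146850747186804
young,cortex,24,FFA(16:1),0.020999999999999998,0.02,0.8099999999999999,0.06,0.13,0.022197358349411167,0.7707519667026056,0.22924803329739435
young,cortex,24,FFA(18:0),0.027999999999999997,0.02,0.8099999999999999,0.06,0.13,0.026388395472784043,0.901811185762609,0.09818881423739095
young,serum,24,FFA(16:0),NA,NA,NA,NA,NA,0.29684087684999994,NA,NA
young,serum,24,FFA(16:1),NA,NA,NA,NA,NA,0.25443503730000006,NA,NA
young,serum,24,FFA(18:0),NA,NA,NA,NA,NA,0.129552263055,NA,NA
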