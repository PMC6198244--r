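"trial_id","treatment","t","n_risk"
"sim_km","chemotherapy",0,150
"sim_km","chemotherapy",3,86
"sim_km","chemotherapy",6,62
"sim_km","chemotherapy",9,33
"sim_km","chemotherapy",12,23
"sim_km","chemotherapy",15,13
"sim_km","chemotherapy",18,7
"sim_km","chemotherapy",21,4
"sim_km","chemotherapy",24,3
"sim_km","ceritinib",0,150
"sim_km","ceritinib",3,105
"sim_km","ceritinib",6,76
"sim_km","ceritinib",9,59
"sim_km","ceritinib",12,38
"sim_km","ceritinib",15,27
"sim_km","ceritinib",18,21
"sim_km","ceritinib",21,15
"sim_km","ceritinib",24,11
"sim_km","crizotinib",0,150
"sim_km","crizotinib",3,116
"sim_km","crizotinib",6,87
"sim_km","crizotinib",9,66
"sim_km","crizotinib",12,51
"sim_km","crizotinib",15,39
"sim_km","crizotinib",18,34
"sim_km","crizotinib",21,29
"sim_km","crizotinib",24,24
"sim_km","alectinib",0,150
"sim_km","alectinib",3,126
"sim_km","alectinib",6,113
"sim_km","alectinib",9,96
"sim_km","alectinib",12,85
"sim_km","alectinib",15,76
"sim_km","alectinib",18,63
"sim_km","alectinib",21,55
"sim_km","alectinib",24,44
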