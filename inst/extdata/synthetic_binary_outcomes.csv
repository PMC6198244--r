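"trial_id","treatment","outcome","events","total"
"sim_alc_crz_1","alectinib","ORR",42,103
"sim_alc_crz_1","crizotinib","ORR",35,104
"sim_alc_crz_2","alectinib","ORR",39,152
"sim_alc_crz_2","crizotinib","ORR",26,151
"sim_cer_chm_1","ceritinib","ORR",95,189
"sim_cer_chm_1","chemotherapy","ORR",20,187
"sim_cer_chm_2","ceritinib","ORR",98,115
"sim_cer_chm_2","chemotherapy","ORR",31,116
"sim_crz_chm_1","crizotinib","ORR",96,173
"sim_crz_chm_1","chemotherapy","ORR",27,174
"sim_crz_chm_2","crizotinib","ORR",141,172
"sim_crz_chm_2","chemotherapy","ORR",65,171
"sim_crz_chm_3","crizotinib","ORR",78,104
"sim_crz_chm_3","chemotherapy","ORR",23,103
"sim_crz_chm_4","crizotinib","ORR",10,14
"sim_crz_chm_4","chemotherapy","ORR",2,14
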