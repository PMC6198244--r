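trial_id,design,treatment,n,pretreatment,phase,median_followup_months,quality_label
hida_2017_jalex,RCT,alectinib,103,ALKI_NAIVE,3,12.0,High risk
hida_2017_jalex,RCT,crizotinib,104,ALKI_NAIVE,3,12.2,High risk
peters_2017_alex,RCT,alectinib,152,ALKI_NAIVE,3,18.6,High risk
peters_2017_alex,RCT,crizotinib,151,ALKI_NAIVE,3,17.6,High risk
soria_2017_ascend4,RCT,ceritinib,189,ALKI_NAIVE,3,NA,Low risk
soria_2017_ascend4,RCT,chemotherapy,187,ALKI_NAIVE,3,NA,Low risk
shaw_2017_ascend5,RCT,ceritinib,115,PRETREATED,3,16.6,Low risk
shaw_2017_ascend5,RCT,chemotherapy,116,PRETREATED,3,16.4,Low risk
shaw_2013_profile1007,RCT,crizotinib,173,ALKI_NAIVE,3,12.2,Medium risk
shaw_2013_profile1007,RCT,chemotherapy,174,ALKI_NAIVE,3,12.1,Medium risk
solomon_2014_profile1014,RCT,crizotinib,172,ALKI_NAIVE,3,10.9,Medium risk
solomon_2014_profile1014,RCT,chemotherapy,171,ALKI_NAIVE,3,7.0,Medium risk
lu_2016_nct01639001,RCT,crizotinib,104,ALKI_NAIVE,3,NA,Medium risk
lu_2016_nct01639001,RCT,chemotherapy,103,ALKI_NAIVE,3,NA,Medium risk
zhao_2015,RCT,crizotinib,14,ALKI_NAIVE,3,12,Medium risk
zhao_2015,RCT,chemotherapy,14,ALKI_NAIVE,3,12,Medium risk
seto_2013_af001jp,SINGLE_ARM,alectinib,46,ALKI_NAIVE,1-2,7.6,6
gadgeel_2014_af002jg,SINGLE_ARM,alectinib,47,PRETREATED,1/2,4.2,3
hida_2016_jp28927,SINGLE_ARM,alectinib,35,MIXED,1/2,NA,5
ou_2016_np28673,SINGLE_ARM,alectinib,138,PRETREATED,2,7.5,6
shaw_2016_np28761,SINGLE_ARM,alectinib,87,PRETREATED,2,9.9,6
iwama_2017,SINGLE_ARM,alectinib,18,MIXED,2,9.8,3
kim_2017_alta,SINGLE_ARM,brigatinib,222,PRETREATED,2,8.0,4
gettinger_2016_nct01449461,SINGLE_ARM,brigatinib,79,MIXED,1/2,17.0,5
kim_2016_ascend1,SINGLE_ARM,ceritinib,255,MIXED,1,11.1,6
crino_2016_ascend2,SINGLE_ARM,ceritinib,140,PRETREATED,2,8.8,5
felip_2016_ascend3,SINGLE_ARM,ceritinib,124,ALKI_NAIVE,2,23.1,3
zhang_2016_ascend6,SINGLE_ARM,ceritinib,103,PRETREATED,1/2,8.3,5
cho_2017_ascend8,SINGLE_ARM,ceritinib,137,ALKI_NAIVE,1,4.1,5
nishio_2015_nct01634763,SINGLE_ARM,ceritinib,20,MIXED,1,NA,5
cadranal_2015,SINGLE_ARM,ceritinib,155,MIXED,1,NA,3
camidge_2012_nct00585195,SINGLE_ARM,crizotinib,149,ALKI_NAIVE,1,16.3,6
blackhall_2017_profile1005,SINGLE_ARM,crizotinib,1066,ALKI_NAIVE,2,NA,6
cui_2015,SINGLE_ARM,crizotinib,72,ALKI_NAIVE,2,NA,6
fujiwara_2016,SINGLE_ARM,crizotinib,8,ALKI_NAIVE,1,NA,5
wu_2015,SINGLE_ARM,crizotinib,21,ALKI_NAIVE,2,NA,3
camidge_2011,SINGLE_ARM,crizotinib,119,ALKI_NAIVE,1,11.0,4
bang_2010,SINGLE_ARM,crizotinib,76,ALKI_NAIVE,2,NA,4
shaw_2017_nct01970865,SINGLE_ARM,lorlatinib,41,MIXED,1,17.4,4
solomon_2017_nct01970865,SINGLE_ARM,lorlatinib,227,MIXED,2,NA,3
horn_2017_nct01625234,SINGLE_ARM,ensartinib,80,MIXED,1/2,NA,4
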