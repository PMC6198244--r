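"trial_id","treatment","t","s"
"sim_km","chemotherapy",0,1
"sim_km","chemotherapy",1,0.84
"sim_km","chemotherapy",2,0.712254936406437
"sim_km","chemotherapy",3,0.602215550163869
"sim_km","chemotherapy",4,0.538927074624128
"sim_km","chemotherapy",5,0.475106763155481
"sim_km","chemotherapy",6,0.439651034561789
"sim_km","chemotherapy",7,0.368739577374403
"sim_km","chemotherapy",8,0.304164888701636
"sim_km","chemotherapy",9,0.238986698265571
"sim_km","chemotherapy",10,0.217260634786883
"sim_km","chemotherapy",11,0.181050528989069
"sim_km","chemotherapy",12,0.166566486669943
"sim_km","chemotherapy",13,0.136874199915736
"sim_km","chemotherapy",14,0.120771352866826
"sim_km","chemotherapy",15,0.112144827662053
"sim_km","chemotherapy",16,0.0948917772525062
"sim_km","chemotherapy",17,0.060385676433413
"sim_km","chemotherapy",18,0.060385676433413
"sim_km","chemotherapy",19,0.0517591512286397
"sim_km","chemotherapy",20,0.0431326260238664
"sim_km","chemotherapy",21,0.0345061008190931
"sim_km","chemotherapy",22,0.0345061008190931
"sim_km","chemotherapy",23,0.0345061008190931
"sim_km","chemotherapy",24,0.0258795756143199
"sim_km","ceritinib",0,1
"sim_km","ceritinib",1,0.89985401459854
"sim_km","ceritinib",2,0.81844592644786
"sim_km","ceritinib",3,0.72947372663581
"sim_km","ceritinib",4,0.680501587564741
"sim_km","ceritinib",5,0.617362265007188
"sim_km","ceritinib",6,0.545802617339134
"sim_km","ceritinib",7,0.502712937022887
"sim_km","ceritinib",8,0.502712937022887
"sim_km","ceritinib",9,0.429855989628266
"sim_km","ceritinib",10,0.407998905409879
"sim_km","ceritinib",11,0.356071771994076
"sim_km","ceritinib",12,0.281890152828644
"sim_km","ceritinib",13,0.243975103032978
"sim_km","ceritinib",14,0.205853993184075
"sim_km","ceritinib",15,0.205853993184075
"sim_km","ceritinib",16,0.190605549244514
"sim_km","ceritinib",17,0.175357105304953
"sim_km","ceritinib",18,0.160108661365392
"sim_km","ceritinib",19,0.152484439395611
"sim_km","ceritinib",20,0.152484439395611
"sim_km","ceritinib",21,0.114363329546709
"sim_km","ceritinib",22,0.0991148856071474
"sim_km","ceritinib",23,0.0914906636373668
"sim_km","ceritinib",24,0.0914906636373668
"sim_km","crizotinib",0,1
"sim_km","crizotinib",1,0.966530612244898
"sim_km","crizotinib",2,0.892698412698413
"sim_km","crizotinib",3,0.77859410430839
"sim_km","crizotinib",4,0.718185941043084
"sim_km","crizotinib",5,0.670818270165209
"sim_km","crizotinib",6,0.589506964690638
"sim_km","crizotinib",7,0.562403196199115
"sim_km","crizotinib",8,0.507660716416893
"sim_km","crizotinib",9,0.472497645378177
"sim_km","crizotinib",10,0.429543313980161
"sim_km","crizotinib",11,0.400421733371336
"sim_km","crizotinib",12,0.371300152762512
"sim_km","crizotinib",13,0.3412801404115
"sim_km","crizotinib",14,0.326112134170989
"sim_km","crizotinib",15,0.295776121689967
"sim_km","crizotinib",16,0.280208957390495
"sim_km","crizotinib",17,0.280208957390495
"sim_km","crizotinib",18,0.264641793091023
"sim_km","crizotinib",19,0.256858210941287
"sim_km","crizotinib",20,0.249074628791551
"sim_km","crizotinib",21,0.233005297901774
"sim_km","crizotinib",22,0.216935967011996
"sim_km","crizotinib",23,0.216935967011996
"sim_km","crizotinib",24,0.20024858493415
"sim_km","alectinib",0,1
"sim_km","alectinib",1,0.959818594104308
"sim_km","alectinib",2,0.932874635568513
"sim_km","alectinib",3,0.858207792207792
"sim_km","alectinib",4,0.837774273345702
"sim_km","alectinib",5,0.810529581529581
"sim_km","alectinib",6,0.769662543805401
"sim_km","alectinib",7,0.71517316017316
"sim_km","alectinib",8,0.694672865105638
"sim_km","alectinib",9,0.660283119308329
"sim_km","alectinib",10,0.646527220989406
"sim_km","alectinib",11,0.618864260633769
"sim_km","alectinib",12,0.59776661538489
"sim_km","alectinib",13,0.583616789053313
"sim_km","alectinib",14,0.576499511138029
"sim_km","alectinib",15,0.547847905171371
"sim_km","alectinib",16,0.526222329967238
"sim_km","alectinib",17,0.504296399551937
"sim_km","alectinib",18,0.460444538721333
"sim_km","alectinib",19,0.423901321362497
"sim_km","alectinib",20,0.416464456075436
"sim_km","alectinib",21,0.409027590788375
"sim_km","alectinib",22,0.379280129640129
"sim_km","alectinib",23,0.364406399066006
"sim_km","alectinib",24,0.3341842443888
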