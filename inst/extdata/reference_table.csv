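"name","mean","se","family","age_band_start","age_band_end","source"
"drC",0.03,NA,"rate",NA,NA,"WHO 2015"
"drO",0.03,NA,"rate",NA,NA,"WHO 2015"
"tpRA_RA",0.952,0.095,"probability",NA,NA,""
"tpRA_MI",0.012,0.001,"probability",NA,NA,"Taylor et al."
"tpRA_CAr",0.001,0.001,"probability",NA,NA,"Taylor et al."
"tpRA_Rv",0.035,0.001,"probability",NA,NA,"Taylor et al."
"tpMI_MI",0.049,0.01,"probability",NA,NA,"Taylor et al."
"tpMI_Rv",0.027,0.004,"probability",NA,NA,"Taylor et al."
"tpMI_D_30to34",0.007,0.001,"probability",30,34,"Taylor et al."
"tpMI_D_35to39",0.009,0.001,"probability",35,39,"Taylor et al."
"tpMI_D_40to44",0.014,0.001,"probability",40,44,"Taylor et al."
"tpMI_D_45to49",0.02,0.002,"probability",45,49,"Taylor et al."
"tpMI_D_50to54",0.032,0.003,"probability",50,54,"Taylor et al."
"tpMI_D_55to59",0.05,0.005,"probability",55,59,"Taylor et al."
"tpMI_D_60to64",0.084,0.008,"probability",60,64,"Taylor et al."
"tpMI_D_65to69",0.131,0.013,"probability",65,69,"Taylor et al."
"tpMI_D_70to74",0.205,0.021,"probability",70,74,"Taylor et al."
"tpMI_D_75to79",0.326,0.033,"probability",75,79,"Taylor et al."
"tpMI_D_80to84",0.508,0.051,"probability",80,84,"Taylor et al."
"tpCAr_D_30to34",0.004,0,"probability",30,34,"Taylor et al."
"tpCAr_D_35to39",0.005,0.001,"probability",35,39,"Taylor et al."
"tpCAr_D_40to44",0.008,0.001,"probability",40,44,"Taylor et al."
"tpCAr_D_45to49",0.012,0.001,"probability",45,49,"Taylor et al."
"tpCAr_D_50to54",0.018,0.002,"probability",50,54,"Taylor et al."
"tpCAr_D_55to59",0.028,0.003,"probability",55,59,"Taylor et al."
"tpCAr_D_60to64",0.048,0.005,"probability",60,64,"Taylor et al."
"tpCAr_D_65to69",0.074,0.007,"probability",65,69,"Taylor et al."
"tpCAr_D_70to74",0.116,0.012,"probability",70,74,"Taylor et al."
"tpCAr_D_75to79",0.185,0.019,"probability",75,79,"Taylor et al."
"tpCAr_D_80to84",0.288,0.029,"probability",80,84,"Taylor et al."
"tpRv_Rv",0.135,0.009,"probability",NA,NA,"Taylor et al."
"tpRv_MI",0.396,0.024,"probability",NA,NA,"Taylor et al."
"tpRv_D_30to34",0.004,0,"probability",30,34,"Taylor et al."
"tpRv_D_35to39",0.005,0.001,"probability",35,39,"Taylor et al."
"tpRv_D_40to44",0.007,0.001,"probability",40,44,"Taylor et al."
"tpRv_D_45to49",0.011,0.001,"probability",45,49,"Taylor et al."
"tpRv_D_50to54",0.017,0.002,"probability",50,54,"Taylor et al."
"tpRv_D_55to59",0.027,0.003,"probability",55,59,"Taylor et al."
"tpRv_D_60to64",0.045,0.005,"probability",60,64,"Taylor et al."
"tpRv_D_65to69",0.071,0.007,"probability",65,69,"Taylor et al."
"tpRv_D_70to74",0.111,0.011,"probability",70,74,"Taylor et al."
"tpRv_D_75to79",0.176,0.018,"probability",75,79,"Taylor et al."
"tpRv_D_80to84",0.274,0.027,"probability",80,84,"Taylor et al."
"dmcRA",19728100,197281,"cost",NA,NA,"INA-CBGs 2016"
"dmcMI",12118800,121188,"cost",NA,NA,"INA-CBGs 2016"
"dmcCAr",7041400,70414,"cost",NA,NA,"INA-CBGs 2016"
"dmcRv",40024100,400241,"cost",NA,NA,"INA-CBGs 2016"
"cHIS",3908568,390856.8,"cost",NA,NA,"Indonesia Secondary Hospital Type B"
"cNHIS",1474656,147465.6,"cost",NA,NA,"Indonesia Secondary Hospital Type B"
"HR_HIS_MI",0.77,0.07,"hazard_ratio",NA,NA,"Taylor et al."
"HR_HIS_CAr",1.07,0.11,"hazard_ratio",NA,NA,"Taylor et al."
"HR_HIS_Rv",0.73,0.04,"hazard_ratio",NA,NA,"Taylor et al."
"uRA",0.78,0.078,"utility",NA,NA,"Lin et al."
"uMI",0.65,0.065,"utility",NA,NA,"Lin et al."
"uCAr",0.68,0.068,"utility",NA,NA,"Lin et al."
"uRv",0.78,0.078,"utility",NA,NA,"Taylor et al."
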