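subject_id,group,index,param,value
S01,SZ,colocality,5/2,0.98
S02,SZ,colocality,5/2,0.92
S03,SZ,colocality,5/2,0.96
S04,SZ,colocality,5/2,0.89
S05,SZ,colocality,5/2,0.89
S06,SZ,colocality,5/2,0.35
S07,SZ,colocality,5/2,0.96
S08,SZ,colocality,5/2,0.98
S09,SZ,colocality,5/2,0.93
S01,SZ,colocality,5/4,0.95
S02,SZ,colocality,5/4,0.88
S03,SZ,colocality,5/4,0.94
S04,SZ,colocality,5/4,0.87
S05,SZ,colocality,5/4,0.88
S06,SZ,colocality,5/4,0.37
S07,SZ,colocality,5/4,0.91
S08,SZ,colocality,5/4,0.97
S09,SZ,colocality,5/4,0.9
S01,SZ,colocality,5/8,0.39
S02,SZ,colocality,5/8,0.38
S03,SZ,colocality,5/8,0.39
S04,SZ,colocality,5/8,0.39
S05,SZ,colocality,5/8,0.39
S06,SZ,colocality,5/8,0.23
S07,SZ,colocality,5/8,0.38
S08,SZ,colocality,5/8,0.39
S09,SZ,colocality,5/8,0.38
S01,SZ,colocality,10/2,1
S02,SZ,colocality,10/2,0.99
S03,SZ,colocality,10/2,0.99
S04,SZ,colocality,10/2,1
S05,SZ,colocality,10/2,0.95
S06,SZ,colocality,10/2,0.61
S07,SZ,colocality,10/2,1
S08,SZ,colocality,10/2,0.99
S09,SZ,colocality,10/2,1
S01,SZ,colocality,10/4,1
S02,SZ,colocality,10/4,0.99
S03,SZ,colocality,10/4,0.99
S04,SZ,colocality,10/4,1
S05,SZ,colocality,10/4,0.96
S06,SZ,colocality,10/4,0.66
S07,SZ,colocality,10/4,1
S08,SZ,colocality,10/4,1
S09,SZ,colocality,10/4,1
S01,SZ,colocality,10/8,0.99
S02,SZ,colocality,10/8,0.97
S03,SZ,colocality,10/8,0.98
S04,SZ,colocality,10/8,0.96
S05,SZ,colocality,10/8,0.96
S06,SZ,colocality,10/8,0.64
S07,SZ,colocality,10/8,0.98
S08,SZ,colocality,10/8,0.99
S09,SZ,colocality,10/8,0.98
S01,SZ,colocality,15/2,1
S02,SZ,colocality,15/2,1
S03,SZ,colocality,15/2,0.99
S04,SZ,colocality,15/2,1
S05,SZ,colocality,15/2,0.98
S06,SZ,colocality,15/2,0.73
S07,SZ,colocality,15/2,1
S08,SZ,colocality,15/2,1
S09,SZ,colocality,15/2,1
S01,SZ,colocality,15/4,1
S02,SZ,colocality,15/4,1
S03,SZ,colocality,15/4,1
S04,SZ,colocality,15/4,1
S05,SZ,colocality,15/4,0.98
S06,SZ,colocality,15/4,0.78
S07,SZ,colocality,15/4,1
S08,SZ,colocality,15/4,1
S09,SZ,colocality,15/4,1
S01,SZ,colocality,15/8,1
S02,SZ,colocality,15/8,1
S03,SZ,colocality,15/8,1
S04,SZ,colocality,15/8,1
S05,SZ,colocality,15/8,0.99
S06,SZ,colocality,15/8,0.79
S07,SZ,colocality,15/8,1
S08,SZ,colocality,15/8,1
S09,SZ,colocality,15/8,1
S01,SZ,dtheta_sample,NA,0.61
S02,SZ,dtheta_sample,NA,0.57
S03,SZ,dtheta_sample,NA,0.68
S04,SZ,dtheta_sample,NA,0.6
S05,SZ,dtheta_sample,NA,0.62
S06,SZ,dtheta_sample,NA,0.89
S07,SZ,dtheta_sample,NA,0.61
S08,SZ,dtheta_sample,NA,0.58
S09,SZ,dtheta_sample,NA,0.62
S01,SZ,dtheta_regr,NA,0.49
S02,SZ,dtheta_regr,NA,0.7
S03,SZ,dtheta_regr,NA,0.11
S04,SZ,dtheta_regr,NA,0.19
S05,SZ,dtheta_regr,NA,0.16
S06,SZ,dtheta_regr,NA,0.33
S07,SZ,dtheta_regr,NA,0.37
S08,SZ,dtheta_regr,NA,0.25
S09,SZ,dtheta_regr,NA,0.2
S01,SZ,area,250,0
S02,SZ,area,250,0.01
S03,SZ,area,250,0.2
S04,SZ,area,250,0.01
S05,SZ,area,250,0.06
S06,SZ,area,250,0.2
S07,SZ,area,250,0.01
S08,SZ,area,250,0
S09,SZ,area,250,0.33
S01,SZ,area,500,0
S02,SZ,area,500,0.08
S03,SZ,area,500,0.2
S04,SZ,area,500,0.11
S05,SZ,area,500,0.09
S06,SZ,area,500,0.49
S07,SZ,area,500,0.03
S08,SZ,area,500,0.03
S09,SZ,area,500,0.34
S01,SZ,area,750,0.01
S02,SZ,area,750,0.17
S03,SZ,area,750,0.16
S04,SZ,area,750,0.04
S05,SZ,area,750,0.22
S06,SZ,area,750,0.49
S07,SZ,area,750,0.06
S08,SZ,area,750,0.07
S09,SZ,area,750,0.34
S01,SZ,area,1000,0
S02,SZ,area,1000,0.13
S03,SZ,area,1000,0.03
S04,SZ,area,1000,0.02
S05,SZ,area,1000,0.35
S06,SZ,area,1000,0.19
S07,SZ,area,1000,0.04
S08,SZ,area,1000,0.02
S09,SZ,area,1000,0.13
S01,SZ,area,1500,0.13
S02,SZ,area,1500,0.43
S03,SZ,area,1500,0.3
S04,SZ,area,1500,0.1
S05,SZ,area,1500,0.38
S06,SZ,area,1500,0.19
S07,SZ,area,1500,0.08
S08,SZ,area,1500,0.13
S09,SZ,area,1500,0.19
C01,CNT,colocality,5/2,0.99
C02,CNT,colocality,5/2,0.98
C03,CNT,colocality,5/2,1
C04,CNT,colocality,5/2,0.98
C05,CNT,colocality,5/2,0.96
C06,CNT,colocality,5/2,0.98
C07,CNT,colocality,5/2,0.99
C08,CNT,colocality,5/2,0.98
C09,CNT,colocality,5/2,0.99
C01,CNT,colocality,5/4,0.97
C02,CNT,colocality,5/4,0.96
C03,CNT,colocality,5/4,0.97
C04,CNT,colocality,5/4,0.97
C05,CNT,colocality,5/4,0.93
C06,CNT,colocality,5/4,0.95
C07,CNT,colocality,5/4,0.96
C08,CNT,colocality,5/4,0.96
C09,CNT,colocality,5/4,0.98
C01,CNT,colocality,5/8,0.39
C02,CNT,colocality,5/8,0.39
C03,CNT,colocality,5/8,0.39
C04,CNT,colocality,5/8,0.39
C05,CNT,colocality,5/8,0.39
C06,CNT,colocality,5/8,0.39
C07,CNT,colocality,5/8,0.39
C08,CNT,colocality,5/8,0.39
C09,CNT,colocality,5/8,0.39
C01,CNT,colocality,10/2,1
C02,CNT,colocality,10/2,1
C03,CNT,colocality,10/2,1
C04,CNT,colocality,10/2,1
C05,CNT,colocality,10/2,1
C06,CNT,colocality,10/2,1
C07,CNT,colocality,10/2,1
C08,CNT,colocality,10/2,1
C09,CNT,colocality,10/2,1
C01,CNT,colocality,10/4,1
C02,CNT,colocality,10/4,1
C03,CNT,colocality,10/4,1
C04,CNT,colocality,10/4,1
C05,CNT,colocality,10/4,1
C06,CNT,colocality,10/4,1
C07,CNT,colocality,10/4,1
C08,CNT,colocality,10/4,1
C09,CNT,colocality,10/4,1
C01,CNT,colocality,10/8,0.99
C02,CNT,colocality,10/8,0.99
C03,CNT,colocality,10/8,1
C04,CNT,colocality,10/8,0.99
C05,CNT,colocality,10/8,0.98
C06,CNT,colocality,10/8,0.99
C07,CNT,colocality,10/8,0.99
C08,CNT,colocality,10/8,0.99
C09,CNT,colocality,10/8,1
C01,CNT,colocality,15/2,1
C02,CNT,colocality,15/2,1
C03,CNT,colocality,15/2,1
C04,CNT,colocality,15/2,1
C05,CNT,colocality,15/2,1
C06,CNT,colocality,15/2,1
C07,CNT,colocality,15/2,1
C08,CNT,colocality,15/2,1
C09,CNT,colocality,15/2,1
C01,CNT,colocality,15/4,1
C02,CNT,colocality,15/4,1
C03,CNT,colocality,15/4,1
C04,CNT,colocality,15/4,1
C05,CNT,colocality,15/4,1
C06,CNT,colocality,15/4,1
C07,CNT,colocality,15/4,1
C08,CNT,colocality,15/4,1
C09,CNT,colocality,15/4,1
C01,CNT,colocality,15/8,1
C02,CNT,colocality,15/8,1
C03,CNT,colocality,15/8,1
C04,CNT,colocality,15/8,1
C05,CNT,colocality,15/8,1
C06,CNT,colocality,15/8,1
C07,CNT,colocality,15/8,1
C08,CNT,colocality,15/8,1
C09,CNT,colocality,15/8,1
C01,CNT,dtheta_sample,NA,0.43
C02,CNT,dtheta_sample,NA,0.49
C03,CNT,dtheta_sample,NA,0.51
C04,CNT,dtheta_sample,NA,0.55
C05,CNT,dtheta_sample,NA,0.55
C06,CNT,dtheta_sample,NA,0.64
C07,CNT,dtheta_sample,NA,0.68
C08,CNT,dtheta_sample,NA,0.49
C09,CNT,dtheta_sample,NA,0.71
C01,CNT,dtheta_regr,NA,0.02
C02,CNT,dtheta_regr,NA,0.07
C03,CNT,dtheta_regr,NA,0.15
C04,CNT,dtheta_regr,NA,0.08
C05,CNT,dtheta_regr,NA,0.1
C06,CNT,dtheta_regr,NA,0.1
C07,CNT,dtheta_regr,NA,0.1
C08,CNT,dtheta_regr,NA,0.08
C09,CNT,dtheta_regr,NA,0.14
C01,CNT,area,250,0.03
C02,CNT,area,250,0
C03,CNT,area,250,0.01
C04,CNT,area,250,0
C05,CNT,area,250,0.04
C06,CNT,area,250,0.27
C07,CNT,area,250,0
C08,CNT,area,250,0.01
C09,CNT,area,250,0.01
C01,CNT,area,500,0.09
C02,CNT,area,500,0.02
C03,CNT,area,500,0.01
C04,CNT,area,500,0.01
C05,CNT,area,500,0.06
C06,CNT,area,500,0.33
C07,CNT,area,500,0
C08,CNT,area,500,0.02
C09,CNT,area,500,0.04
C01,CNT,area,750,0.1
C02,CNT,area,750,0.06
C03,CNT,area,750,0.02
C04,CNT,area,750,0.06
C05,CNT,area,750,0.08
C06,CNT,area,750,0.31
C07,CNT,area,750,0
C08,CNT,area,750,0.02
C09,CNT,area,750,0.06
C01,CNT,area,1000,0.04
C02,CNT,area,1000,0
C03,CNT,area,1000,0.02
C04,CNT,area,1000,0.07
C05,CNT,area,1000,0.06
C06,CNT,area,1000,0.24
C07,CNT,area,1000,0.01
C08,CNT,area,1000,0.02
C09,CNT,area,1000,0.02
C01,CNT,area,1500,0.04
C02,CNT,area,1500,0.09
C03,CNT,area,1500,0.14
C04,CNT,area,1500,0.12
C05,CNT,area,1500,0.06
C06,CNT,area,1500,0.4
C07,CNT,area,1500,0.14
C08,CNT,area,1500,0.16
C09,CNT,area,1500,0.05
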