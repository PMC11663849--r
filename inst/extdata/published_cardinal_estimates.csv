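source,strain,param,value
table_ctmi,ICIPE 20,mu_opt,2.11
table_ctmi,ICIPE 20,Tmin,12.10
table_ctmi,ICIPE 20,Topt,28.33
table_ctmi,ICIPE 20,Tmax,40.78
table_ctmi,ICIPE 41,mu_opt,1.72
table_ctmi,ICIPE 41,Tmin,11.63
table_ctmi,ICIPE 41,Topt,27.16
table_ctmi,ICIPE 41,Tmax,41.18
table_ctmi,ICIPE 62,mu_opt,1.49
table_ctmi,ICIPE 62,Tmin,12.77
table_ctmi,ICIPE 62,Topt,26.18
table_ctmi,ICIPE 62,Tmax,39.60
table_ctmi,ICIPE 78,mu_opt,2.06
table_ctmi,ICIPE 78,Tmin,13.19
table_ctmi,ICIPE 78,Topt,26.68
table_ctmi,ICIPE 78,Tmax,40.17
table_ctmi,ICIPE 603,mu_opt,1.91
table_ctmi,ICIPE 603,Tmin,8.29
table_ctmi,ICIPE 603,Topt,29.81
table_ctmi,ICIPE 603,Tmax,42.12
table_lactin1,ICIPE 20,a,0.000060
table_lactin1,ICIPE 20,Tmin,-2.4
table_lactin1,ICIPE 20,Tmax,40.57
table_lactin1,ICIPE 41,a,0.000033
table_lactin1,ICIPE 41,Tmin,-9.35
table_lactin1,ICIPE 41,Tmax,40.75
table_lactin1,ICIPE 62,a,0.000023
table_lactin1,ICIPE 62,Tmin,-1.49
table_lactin1,ICIPE 62,Tmax,39.7
table_lactin1,ICIPE 78,a,0.0000037
table_lactin1,ICIPE 78,Tmin,-1.07
table_lactin1,ICIPE 78,Tmax,40.13
table_lactin1,ICIPE 603,a,0.0000054
table_lactin1,ICIPE 603,Tmin,-1.73
table_lactin1,ICIPE 603,Tmax,41.59
reported_ctmi,ICIPE 20,Tmin,9.0
reported_ctmi,ICIPE 20,Topt,29.5
reported_ctmi,ICIPE 20,Tmax,35.8
reported_ctmi,ICIPE 41,Tmin,-3.7
reported_ctmi,ICIPE 41,Topt,30.8
reported_ctmi,ICIPE 41,Tmax,35.2
reported_ctmi,ICIPE 62,Tmin,8.1
reported_ctmi,ICIPE 62,Topt,27.5
reported_ctmi,ICIPE 62,Tmax,35.6
reported_ctmi,ICIPE 78,Tmin,13.1
reported_ctmi,ICIPE 78,Topt,26.7
reported_ctmi,ICIPE 78,Tmax,40.2
reported_ctmi,ICIPE 603,Tmin,9.8
reported_ctmi,ICIPE 603,Topt,31.1
reported_ctmi,ICIPE 603,Tmax,45.4
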