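study,stratum,analyte,parameter,units,n,mean,sd
A,normal,telavancin,t_half,h,6,6.9,0.6
A,mild,telavancin,t_half,h,6,9.6,2.9
A,moderate,telavancin,t_half,h,6,10.6,2.4
A,severe,telavancin,t_half,h,4,14.5,1.3
A,esrd,telavancin,t_half,h,6,11.8,2.8
A,normal,telavancin,cmax,ug/mL,6,70.6,11.2
A,mild,telavancin,cmax,ug/mL,6,65.9,2.7
A,moderate,telavancin,cmax,ug/mL,6,65.8,12.1
A,severe,telavancin,cmax,ug/mL,4,71.8,7.1
A,esrd,telavancin,cmax,ug/mL,6,52.1,10.1
A,normal,telavancin,auc_0_inf,ug.h/mL,6,560,93
A,mild,telavancin,auc_0_inf,ug.h/mL,6,633,101
A,moderate,telavancin,auc_0_inf,ug.h/mL,6,721,200
A,severe,telavancin,auc_0_inf,ug.h/mL,4,1220,120
A,esrd,telavancin,auc_0_inf,ug.h/mL,6,1010,341
A,normal,telavancin,cl,mL/h/kg,6,13.7,2.1
A,mild,telavancin,cl,mL/h/kg,6,12.1,1.9
A,moderate,telavancin,cl,mL/h/kg,6,11.1,3.3
A,severe,telavancin,cl,mL/h/kg,4,6.18,0.63
A,esrd,telavancin,cl,mL/h/kg,6,8.18,2.65
A,normal,telavancin,vss,mL/kg,6,131,16
A,mild,telavancin,vss,mL/kg,6,157,19
A,moderate,telavancin,vss,mL/kg,6,156,24
A,severe,telavancin,vss,mL/kg,4,136,10
A,esrd,telavancin,vss,mL/kg,6,157,27
A,normal,telavancin,protein_binding_pct,%,6,86.5,1.3
A,mild,telavancin,protein_binding_pct,%,6,87.5,1.0
A,moderate,telavancin,protein_binding_pct,%,6,87.8,1.1
A,severe,telavancin,protein_binding_pct,%,4,86.7,1.2
A,esrd,telavancin,protein_binding_pct,%,6,87.6,1.0
A,normal,,weight,kg,6,79,10
A,mild,,weight,kg,7,76,15
A,moderate,,weight,kg,6,69,11
A,severe,,weight,kg,4,80,17
A,esrd,,weight,kg,6,81,23
A,esrd,telavancin,cl_hd_ml_min,mL/min,6,4.5,NA
A,esrd,telavancin,cl_hd_ml_h,mL/h,6,271,NA
B,normal,telavancin,t_half,h,14,6.5,0.9
B,mild,telavancin,t_half,h,13,7.8,2.0
B,moderate,telavancin,t_half,h,8,8.1,1.5
B,severe,telavancin,t_half,h,8,11.8,6.7
B,normal,telavancin,cmax,ug/mL,14,76.7,8.6
B,mild,telavancin,cmax,ug/mL,13,74.2,7.3
B,moderate,telavancin,cmax,ug/mL,8,78.0,4.5
B,severe,telavancin,cmax,ug/mL,8,83.2,13.1
B,normal,telavancin,auc_0_inf,ug.h/mL,14,539,99
B,mild,telavancin,auc_0_inf,ug.h/mL,13,606,139
B,moderate,telavancin,auc_0_inf,ug.h/mL,8,936,182
B,severe,telavancin,auc_0_inf,ug.h/mL,8,1397,297
B,normal,telavancin,cl,mL/h/kg,14,17.0,3.2
B,mild,telavancin,cl,mL/h/kg,13,15.2,4.6
B,moderate,telavancin,cl,mL/h/kg,8,9.5,2.0
B,severe,telavancin,cl,mL/h/kg,8,6.5,1.5
B,normal,telavancin,vss,mL/kg,14,155.4,30.2
B,mild,telavancin,vss,mL/kg,13,159.5,34.5
B,moderate,telavancin,vss,mL/kg,8,157.8,41.7
B,severe,telavancin,vss,mL/kg,8,141.9,17.7
B,normal,telavancin,ae_0_t,mg,14,436,91
B,mild,telavancin,ae_0_t,mg,13,397,100
B,moderate,telavancin,ae_0_t,mg,8,368,91
B,severe,telavancin,ae_0_t,mg,8,207,62
B,normal,telavancin,ae_0_t_pct,%,14,62.8,9.0
B,mild,telavancin,ae_0_t_pct,%,13,58.2,11.5
B,moderate,telavancin,ae_0_t_pct,%,8,48.4,8.7
B,severe,telavancin,ae_0_t_pct,%,8,28.0,4.3
B,normal,telavancin,ae_0_inf,mg,14,435,91
B,mild,telavancin,ae_0_inf,mg,13,396,100
B,moderate,telavancin,ae_0_inf,mg,8,375,96
B,severe,telavancin,ae_0_inf,mg,8,208,60
B,normal,telavancin,ae_0_inf_pct,%,14,62.7,9.1
B,mild,telavancin,ae_0_inf_pct,%,13,58.2,11.6
B,moderate,telavancin,ae_0_inf_pct,%,8,48.4,9.3
B,severe,telavancin,ae_0_inf_pct,%,8,28.2,3.9
B,normal,telavancin,cl_r,mL/h/kg,14,10.5,1.9
B,mild,telavancin,cl_r,mL/h/kg,13,8.8,3.3
B,moderate,telavancin,cl_r,mL/h/kg,8,4.7,1.6
B,severe,telavancin,cl_r,mL/h/kg,8,1.9,0.7
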