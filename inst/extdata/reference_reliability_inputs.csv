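metric,mean1,sd1,mean2,sd2,sem
hr,60.65,10.58,60.19,10.04,0.19
sbp_mean,132.65,16.90,131.91,20.75,0.48
sbp_sd,5.28,2.50,5.43,2.30,0.16
sbp_cv,4.01,1.88,4.11,1.74,0.12
sbp_vim,2.02,0.44,2.02,0.35,0.03
sbp_arv,1.69,0.99,1.77,1.02,0.05
delta_sbp,33.32,12.15,34.07,12.23,1.13
dbp_mean,77.42,10.36,77.55,10.50,0.24
dbp_sd,2.93,1.97,3.08,2.15,0.13
dbp_cv,3.92,2.93,4.14,3.35,0.19
dbp_vim,2.30,1.26,2.30,1.77,0.11
dbp_arv,1.90,1.39,1.99,1.35,0.08
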