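task,feature_set,n,mean_tp,mean_fn,mean_fp,mean_tn,tpr,sd_tpr,fpr,sd_fpr,accuracy,sd_accuracy,prose_accuracy_pct,prose_tpr_pct,prose_fpr_pct
smoker,all,36,32.70,23.30,21.35,30.65,58.39,6.44,41.06,4.44,58.66,4.63,NA,NA,NA
smoker,intensity,18,27.30,28.70,27.90,24.10,48.75,5.18,53.65,6.20,47.59,3.30,48,NA,NA
smoker,tau_m,18,34.90,21.10,21.15,30.85,62.32,4.85,40.67,4.48,60.88,3.14,61,NA,NA
smoker,tau_ssc,9,33.50,22.50,33.40,18.60,59.82,3.50,64.23,5.35,48.24,3.26,48,NA,NA
smoker,tau_lsc,9,33.25,22.75,18.90,33.10,59.38,6.00,36.35,4.75,61.44,3.91,61,NA,NA
smoker,tau_ir,8,38.80,17.20,18.05,33.95,69.29,4.78,34.71,5.91,67.36,3.04,67,NA,NA
smoker,tau_or,8,27.25,28.75,19.05,32.95,48.66,3.33,36.63,4.73,55.74,2.68,56,NA,NA
smoker,tau_ir_ssc_or_lsc,8,35.00,21.00,17.05,34.95,62.50,3.66,32.79,5.62,64.77,3.54,65,NA,NA
smoker,tau_or_ssc_ir_lsc,8,26.80,29.20,27.45,24.55,47.86,5.43,52.79,7.36,47.55,3.24,48,NA,NA
smoker,ttest_top3,3,40.65,15.35,16.40,35.60,72.59,3.88,31.54,4.49,70.60,2.36,71,NA,NA
heavy_smoker,all,36,11.85,16.15,9.50,42.50,42.32,7.34,18.27,2.75,67.94,3.02,NA,NA,NA
heavy_smoker,intensity,18,8.15,19.85,13.45,38.55,29.11,8.70,25.87,3.67,58.38,3.97,58,NA,NA
heavy_smoker,tau_m,18,14.30,13.70,8.45,43.55,51.07,3.41,16.25,3.25,72.31,2.72,72,51,16
heavy_smoker,tau_ssc,9,6.05,21.95,14.50,37.50,21.61,7.78,27.88,3.96,54.44,3.43,54,NA,NA
heavy_smoker,tau_lsc,9,11.75,16.25,10.15,41.85,41.96,5.16,19.52,4.00,67.00,2.60,67,NA,NA
heavy_smoker,tau_ir,8,15.30,12.70,10.70,41.30,54.64,6.40,20.58,2.28,70.75,2.72,71,NA,NA
heavy_smoker,tau_or,8,11.95,16.05,10.95,41.05,42.68,6.03,21.06,5.52,66.25,3.49,66,NA,NA
heavy_smoker,tau_ir_ssc_or_lsc,8,18.05,9.95,6.40,45.60,64.46,5.23,12.31,4.19,79.56,3.31,80,NA,NA
heavy_smoker,tau_or_ssc_ir_lsc,8,9.15,18.85,11.90,40.10,32.68,5.90,22.88,5.47,61.56,3.75,62,NA,NA
heavy_smoker,ttest_top3,3,19.10,8.90,7.10,44.90,68.21,6.07,13.65,2.91,80.00,2.98,80,NA,NA
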