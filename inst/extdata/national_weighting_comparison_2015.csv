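survey,indicator,truth,avg_unweighted,avg_weighted,bias_diff,bias_ci_low,bias_ci_high,bias_sig,var_unweighted,var_weighted,log_var_ratio,lvr_ci_low,lvr_ci_high,lvr_sig,var_ratio,mse_unweighted,mse_weighted,log_mse_ratio,lmr_ci_low,lmr_ci_high,lmr_sig
tspa,Client had no problem with the amount of time waited,70.0,66.3,69.8,-3.6,-5.6,-1.4,1,0.1,0.2,-0.701,-0.733,-0.478,1,0.496,1.5,0.2,1.278,1.595,1.922,1
tspa,Client had no problem with privacy from having others hear,96.8,96.8,96.8,0,-0.6,0.7,0,0.0,0.0,-0.536,-0.726,-0.518,1,0.585,0.0,0.0,-0.595,-0.69,-0.553,1
tspa,Client had no problem with the cleanliness of the facility,85.3,85.7,85.4,0.3,-1.2,1.9,0,0.1,0.1,-0.453,-0.564,-0.314,1,0.636,0.1,0.1,-0.326,-0.532,-0.321,1
tspa,Provider weighed the client,80.8,86.0,80.8,5.2,1.8,8.7,1,0.2,0.7,-1.172,-1.36,-1.134,1,0.310,2.9,0.7,0.811,0.734,0.951,1
tspa,Provider asked about or performed syphilis test,13.7,17.4,13.6,3.8,1.4,6.2,1,0.2,0.3,-0.129,-0.192,0.042,0,0.879,1.6,0.3,1.268,1.255,1.536,1
tspa,Provider provided or prescribed tetanus toxoid vaccine,53.5,58.1,53.6,4.5,1.1,8,1,0.3,0.6,-0.922,-0.937,-0.671,1,0.398,2.4,0.6,0.746,0.598,0.772,1
tspa,Hemoglobin test available at the facility,29.5,52.0,29.4,22.6,19.7,25.5,1,0.3,0.4,-0.269,-0.493,-0.224,1,0.764,51.1,0.4,4.258,4.256,4.515,1
tspa,TT vaccine available at the facility,86.4,90.3,86.4,3.9,1.8,5.9,1,0.1,0.3,-1.109,-1.27,-1.029,1,0.330,1.6,0.3,1.135,1.106,1.236,1
tspa,IPT drug available at the facility,63.2,67.1,63.3,3.8,0.8,7.1,1,0.2,0.5,-0.854,-1.043,-0.799,1,0.426,1.8,0.5,0.678,0.578,0.743,1
tspa,ITNs or ITN vouchers available at facility,9.8,17.7,9.8,7.9,5.8,9.9,1,0.2,0.2,-0.016,-0.258,0.028,0,0.984,6.4,0.2,2.944,2.824,3.023,1
tdhs,ANC1 coverage,98.0,98.0,98.0,0,-0.2,0.3,0,0.0,0.0,-0.384,-0.415,-0.222,1,0.681,0.0,0.0,-0.292,-0.294,-0.124,1
tdhs,ANC4+ coverage,50.9,49.3,50.9,-1.6,-2.5,-0.5,1,0.1,0.1,-0.328,-0.42,-0.248,1,0.720,0.3,0.1,0.678,0.627,0.772,1
tdhs,IPTp coverage,35.8,35.3,35.8,-0.5,-1.4,0.3,0,0.1,0.1,-0.345,-0.435,-0.27,1,0.708,0.1,0.1,-0.159,-0.276,-0.117,1
tdhs,Iron supplementation coverage,21.8,20.9,21.8,-0.9,-1.7,-0.2,1,0.0,0.1,-0.315,-0.416,-0.233,1,0.730,0.1,0.1,0.392,0.357,0.56,1
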