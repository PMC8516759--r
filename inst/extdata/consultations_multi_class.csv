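video,patient_manual_s,caregiver_manual_s,researcher_manual_s,patient_algo_s,caregiver_algo_s,researcher_algo_s,delta_s,normalized_delta_pct,kappa,reid_accuracy_pct
1,30.16,0.00,0.28,30.44,0.00,0.16,-0.16,0.27,0.93,96.26
2,26.90,0.00,0.10,26.50,0.00,0.10,0.40,0.66,0.88,94.18
3,28.76,0.00,1.32,30.16,0.00,1.24,-1.32,2.20,0.92,95.94
4,34.20,0.00,1.16,35.72,0.00,0.84,-1.20,1.98,0.93,96.50
5,24.80,0.00,0.00,26.00,0.00,0.00,-1.20,1.99,0.96,98.01
6,24.56,0.00,0.08,26.56,0.00,0.12,-2.04,3.40,0.91,95.80
7,24.00,10.36,0.04,23.68,10.80,0.08,-0.16,0.27,0.91,94.53
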