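video,duration_s,face_gaze_manual_s,face_gaze_algo_s,delta_s,normalized_delta_pct,kappa
1,59.84,30.44,30.60,-0.16,0.27,0.97
2,60.50,27.00,26.60,0.40,0.66,0.89
3,60.04,30.08,31.40,-1.32,2.20,0.94
4,60.46,35.36,36.56,-1.20,1.98,0.96
5,60.20,24.80,26.00,-1.20,1.99,0.98
6,60.00,24.64,26.68,-2.04,3.40,0.91
7,60.00,34.40,34.56,-0.16,0.27,0.90
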