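video,shape,duration_s,face_gaze_manual_s,face_gaze_algo_s,delta_s,normalized_delta_pct,kappa
6,rectangle,1102.76,173.92,183.52,-9.60,0.87,0.95
6,oval,1102.76,174.60,183.52,-8.92,0.81,0.95
7,rectangle,758.92,229.16,239.40,-10.24,1.35,0.89
7,oval,758.92,209.24,239.40,-30.16,3.97,0.87
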