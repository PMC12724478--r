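dimension,level,decrement
mobility,2,0.035
mobility,3,0.080
mobility,4,0.200
mobility,5,0.336
self_care,2,0.040
self_care,3,0.090
self_care,4,0.210
self_care,5,0.320
usual_activities,2,0.030
usual_activities,3,0.060
usual_activities,4,0.110
usual_activities,5,0.175
pain_discomfort,2,0.045
pain_discomfort,3,0.110
pain_discomfort,4,0.270
pain_discomfort,5,0.415
anxiety_depression,2,0.050
anxiety_depression,3,0.120
anxiety_depression,4,0.280
anxiety_depression,5,0.415
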