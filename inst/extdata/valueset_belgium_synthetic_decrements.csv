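dimension,level,decrement
mobility,2,0.040
mobility,3,0.070
mobility,4,0.210
mobility,5,0.300
self_care,2,0.040
self_care,3,0.070
self_care,4,0.180
self_care,5,0.260
usual_activities,2,0.040
usual_activities,3,0.086
usual_activities,4,0.180
usual_activities,5,0.250
pain_discomfort,2,0.050
pain_discomfort,3,0.085
pain_discomfort,4,0.220
pain_discomfort,5,0.360
anxiety_depression,2,0.060
anxiety_depression,3,0.151
anxiety_depression,4,0.260
anxiety_depression,5,0.362
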