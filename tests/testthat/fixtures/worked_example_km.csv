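"time","n_risk","n_event","n_censor","survival"
3.52512959617162,12,1,0,0.916666666666667
6.59209452739611,11,1,0,0.833333333333333
19.3233018844085,10,1,0,0.75
31.0026808228016,9,1,0,0.666666666666667
110.448204848212,8,1,0,0.583333333333333
110.453723272453,7,1,0,0.5
117.278519529307,6,1,0,0.416666666666667
128.056143911275,5,0,1,0.416666666666667
157.705026045497,4,0,1,0.416666666666667
244.331621734703,3,1,0,0.277777777777778
274.292703089601,2,0,1,0.277777777777778
388.69742555284,1,1,0,0
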