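age_start,age_width,residence,bc_incidence_1e5,all_cause_mortality_1e5,bc_mortality_1e5
30,5,rural,11.5193929173693,46,2.87984822934233
35,5,rural,26.8785834738617,63.25,6.71964586846543
40,5,rural,46.0775716694772,97.75,11.5193929173693
45,5,rural,65.2765598650927,149.5,16.3191399662732
50,5,rural,76.7959527824621,230,19.1989881956155
55,5,rural,76.7959527824621,379.5,19.1989881956155
60,5,rural,76.7959527824621,690,19.1989881956155
65,5,rural,76.7959527824621,1380,19.1989881956155
70,5,rural,76.7959527824621,2760,19.1989881956155
75,5,rural,76.7959527824621,5520,19.1989881956155
80,5,rural,76.7959527824621,10925,19.1989881956155
30,5,urban,18.1305227655986,40,4.53263069139966
35,5,urban,42.3045531197302,55,10.5761382799325
40,5,urban,72.5220910623946,85,18.1305227655986
45,5,urban,102.739629005059,130,25.6849072512648
50,5,urban,120.870151770658,200,30.2175379426644
55,5,urban,120.870151770658,330,30.2175379426644
60,5,urban,120.870151770658,600,30.2175379426644
65,5,urban,120.870151770658,1200,30.2175379426644
70,5,urban,120.870151770658,2400,30.2175379426644
75,5,urban,120.870151770658,4800,30.2175379426644
80,5,urban,120.870151770658,9500,30.2175379426644
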