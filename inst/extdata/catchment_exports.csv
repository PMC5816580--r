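system,pct_fertilized,nox_export,tn_export
Wingan River,0.49,0.06,1.7
Cann River,2.0,0.08,0.22
Genoa River,4.7,0.11,0.62
Aire River,13,0.74,1.0
Gellibrand River,25,1.3,3.1
Merriman Creek,35,0.38,1.1
Tarra River,38,1.6,2.5
Werribee River,56,0.11,0.35
Patterson River,57,0.33,1.2
Glenelg River,63,0.24,0.65
Kororoit Creek,82,0.28,0.56
Tarwin River,85,3.1,6.1
Curdies River,86,0.70,2.4
Bass River,92,3.1,7.7
Moyne River,98,0.79,1.9
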