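waveform,displacement_pp_mm,arm,area95_cm2,area5_cm2
standstill,0,standstill,5.36,18.53
sine,10,uncompensated,3.78,18.93
sine,20,uncompensated,1.87,20.99
sine,30,uncompensated,0,23.67
sine,10,compensated,4.6,17.39
sine,20,compensated,4.303,17.54
sine,30,compensated,4.12,17.4
breathing,10,uncompensated,4.06,18.44
breathing,20,uncompensated,2.3,23
breathing,30,uncompensated,0.17,24.58
breathing,10,compensated,5.03,19.03
breathing,20,compensated,4.57,18.21
breathing,30,compensated,4.8,19.18
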