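waveform,displacement_pp_mm,arm,gamma_pass_pct
sine,10,uncompensated,100
sine,20,uncompensated,92
sine,30,uncompensated,0
sine,10,compensated,100
sine,20,compensated,100
sine,30,compensated,100
breathing,10,uncompensated,100
breathing,20,uncompensated,84
breathing,30,uncompensated,39.6
breathing,10,compensated,100
breathing,20,compensated,100
breathing,30,compensated,100
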