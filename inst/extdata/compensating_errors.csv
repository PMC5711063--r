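waveform,displacement_pp_mm,rss_position_error_mm,couch_position_error_mm,compensating_error_mm
sine,10,0.58,0.62,0.92
sine,20,0.98,1.04,1.65
sine,30,1.42,1.42,2.75
breathing,10,0.45,0.48,1.14
breathing,20,0.85,0.81,1.70
breathing,30,1.28,0.87,2.57
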