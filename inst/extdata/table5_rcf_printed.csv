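analyte,rcf_printed
p_hydroxybenzyl_alcohol,2.1090
parishin_E,0.7589
p_hydroxy_benzaldehyde,2.8194
parishin_B,1.1156
parishin_C,1.6771
parishin_A,0.6316
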