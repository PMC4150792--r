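name	rut_end	zone_start	zone_end
tR1_like	120	190	265
trpt_like	135	220	300
trac_like	210	595	635
tyag_like	87	470	520
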