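event,count
mi,639
stroke,262
revasc,965
cv_death,240
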