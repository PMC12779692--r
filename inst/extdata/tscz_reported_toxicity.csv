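compound_id,endpoint,chronic,concentration,reported_class
TSCZ4,fish_96h,FALSE,2.511,toxic
TSCZ5,fish_96h,FALSE,1.059,toxic
TSCZ4,daphnia_48h,FALSE,1.747,toxic
TSCZ1,fish_96h,FALSE,0.263,very_toxic
TSCZ6,fish_96h,FALSE,0.903,very_toxic
TSCZ2,algae_96h,FALSE,0.713,very_toxic
TSCZ3,algae_96h,FALSE,0.553,very_toxic
TSCZ3,daphnia_chv,TRUE,0.047,very_toxic
TSCZ2,daphnia_chv,TRUE,0.063,very_toxic
TSCZ6,fish_chv,TRUE,0.098,very_toxic
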