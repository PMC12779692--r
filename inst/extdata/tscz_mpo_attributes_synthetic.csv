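compound_id,log_kow,log_d,tpsa,pka,molecular_weight,hbd_count
TSCZ1,4.2,2.6,75,7.6,289.3,2
TSCZ2,4.75,2.6,75,7.5,305.8,2
TSCZ3,5.385,2.8,75,7.4,350.2,2
TSCZ4,4.3,2.7,70,7.8,305.4,2
TSCZ5,4.8,2.5,70,7.7,321.8,2
TSCZ6,5.3,2.7,70,7.6,366.3,2
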