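compound_id,e_homo_ev,e_lumo_ev
TSCZ1,-5.86,-2.224
TSCZ2,-5.866,-2.232
TSCZ3,-5.867,-2.233
TSCZ4,-5.844,-2.128
TSCZ5,-5.85,-2.136
TSCZ6,-5.851,-2.137
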