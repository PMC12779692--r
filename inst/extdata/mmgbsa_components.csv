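complex,e_vdw,e_ele,g_gb,g_sa,minus_t_ds,dg_bind_printed,dg_bind_sd_printed
GNT-AChE,-41.56,-5.65,28.6,-3.11,4.83,-16.89,2.16
TSCZ4-AChE,-43.94,-5.33,29.15,-4.01,6.32,-17.81,2.59
TSCZ1-AChE,-44.79,-5.97,29.82,-3.53,5.83,-18.64,2.32
8U2-BChE,-35.56,-8.43,19.93,-7.45,5.24,-26.27,3.89
TSCZ4-BChE,-31.56,-6.43,16.66,-4.45,6.24,-19.54,2.73
TSCZ6-BChE,-32.93,-7.19,18.04,-5.67,4.89,-22.86,3.02
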