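direction,replicate,recovery_pct,transport_rate_nmol_h,papp_1e6_cm_s
AtoB,A,82.7,0.56,13.36
AtoB,B,86.4,0.48,11.01
AtoB,C,84.5,0.56,13.23
BtoA,A,85.9,0.49,11.36
BtoA,B,88.7,0.46,10.36
BtoA,C,78.3,0.53,13.36
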