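# dialect: relative_transition
# reference: SYNWT_micro001
# reported_macro_pka: 7.24
compound_id,microstate_id,formal_charge,conformer_id,free_energy_kcal
SYNWT,SYNWT_micro001,0,conf001,0.0
SYNWT,SYNWT_micro002,-1,conf001,4.9126943941
SYNWT,SYNWT_micro002,-1,conf002,4.9126943941
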