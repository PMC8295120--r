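# dialect: relative_transition
# reference: SYNFLIP_micro001
# reported_macro_pka: 8.11
compound_id,microstate_id,formal_charge,conformer_id,free_energy_kcal
SYNFLIP,SYNFLIP_micro001,0,conf001,0.0
SYNFLIP,SYNFLIP_micro004,-1,conf001,5.7434798953
SYNFLIP,SYNFLIP_micro005,0,conf001,11.0640066964
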