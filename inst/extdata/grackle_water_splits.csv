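bird_id,experiment_id,n_functional,n_other
Tequila,EXP3_HVL,33,10
Margarita,EXP3_HVL,41,8
Cerveza,EXP3_HVL,36,19
Batido,EXP3_HVL,38,13
Horchata,EXP3_HVL,18,14
Refresco,EXP3_HVL,46,21
Tequila,EXP4_MAGIC,19,11
Margarita,EXP4_MAGIC,17,39
Cerveza,EXP4_MAGIC,10,29
Batido,EXP4_MAGIC,9,28
Horchata,EXP4_MAGIC,16,16
Refresco,EXP4_MAGIC,17,18
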