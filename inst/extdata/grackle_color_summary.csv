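bird_id,sex,exp1_trials,refresher_trials,exp2_trials,exp2_status
Tequila,M,30,30,100,complete
Margarita,F,30,10,100,complete
Cerveza,F,30,10,90,complete
Michelada,F,40,10,70,complete
Horchata,F,30,50,130,complete
Refresco,M,20,80,70,complete
Batido,M,30,30,,incomplete
Jugo,M,40,10,80,complete
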