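patient_id,age_months,value,P1,P2,P3
Jstar,15,3.00,0,1,1
Jstar,30,7.00,0,1,1
Jstar,45,13.25,0,1,1
Jstar,60,13.25,0,1,1
Jstar,75,15.50,0,1,1
Jstar,90,19.25,0,1,1
Jstar,105,25.00,0,1,1
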