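class_name,x,y,z,group,side
AIBL,0.40,0.00,0.50,backward,L
AIBR,0.40,0.00,-0.50,backward,R
AVEL,0.05,0.00,0.50,backward,L
AVER,0.05,0.00,-0.50,backward,R
AVAL,-0.35,0.00,0.50,backward,L
AVAR,-0.35,0.00,-0.50,backward,R
RIML,-0.75,0.05,0.45,backward,L
RIMR,-0.75,0.05,-0.45,backward,R
VA01,-1.30,-0.30,0.05,backward,none
DA01,-1.80,-0.25,-0.05,backward,none
AVBL,-0.15,0.25,0.55,forward,L
AVBR,-0.15,0.25,-0.55,forward,R
RIBL,0.10,0.20,0.55,forward,L
RIBR,0.10,0.20,-0.55,forward,R
RMEL,0.60,0.10,0.45,forward,L
RMER,0.60,0.10,-0.45,forward,R
RMED,0.65,0.40,0.00,forward,none
RMEV,0.65,-0.35,0.00,forward,none
RID,-0.55,0.50,0.00,forward,none
RIS,-0.70,-0.15,0.10,forward,none
DB01,-1.55,-0.20,0.10,forward,none
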