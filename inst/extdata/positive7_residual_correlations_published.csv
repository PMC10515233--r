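item,q4,q5,q6,q7,q9,q10,q13
q4,1,0.12,-0.07,-0.19,-0.05,-0.26,-0.27
q5,0.12,1,0.12,-0.19,-0.17,-0.21,-0.25
q6,-0.07,0.12,1,-0.07,-0.25,-0.18,-0.25
q7,-0.19,-0.19,-0.07,1,-0.13,0,-0.24
q9,-0.05,-0.17,-0.25,-0.13,1,-0.13,-0.28
q10,-0.26,-0.21,-0.18,0,-0.13,1,0.03
q13,-0.27,-0.25,-0.25,-0.24,-0.28,0.03,1
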