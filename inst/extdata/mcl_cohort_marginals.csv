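variable,level,count,denominator,printed_pct,digits
sex,male,90,120,75,0
sex,female,30,120,25,0
stage,I,0,120,0,0
stage,II,5,120,4,0
stage,III,11,120,9,0
stage,IV,104,120,87,0
blastoid,yes,16,120,13,0
b_symptoms,yes,29,120,24,0
ldh,normal,77,120,64,0
ldh,increased,43,120,36,0
b2_microglobulin,normal,82,120,68,0
b2_microglobulin,increased,38,120,32,0
bulky,yes,16,120,13,0
splenomegaly,yes,49,120,41,0
ki67,low,68,106,64,0
ki67,high,38,106,36,0
mipi,low,36,120,30,0
mipi,intermediate,45,120,37.5,1
mipi,high,39,120,32.5,1
response,complete,83,118,70,0
response,not_complete,35,118,30,0
bone_marrow,involved,34,120,28,0
gastrointestinal,involved,16,120,13,0
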