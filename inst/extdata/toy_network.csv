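Components,Connect,Inputs,Outputs,0,5,10,15,20,25,30,35
C1,Yes,A,,20,0,0,0,0,0,0,0
,Yes,D,,,,,,,,,
,Yes,,B,,,,,,,,
C2,Yes,B,,,,,,,,,
,Yes,,C,,,,,,,,
C3,Yes,B,,,,,,,,,
,No,C,,,,,,,,,
,Yes,,D,,,,,,,,
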