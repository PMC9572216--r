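id,kind,foot,x_mm,y_mm
P01,pressure,L,-18,25
P02,pressure,L,18,25
P03,pressure,L,-15,50
P04,pressure,L,15,50
P05,pressure,L,-20,105
P06,pressure,L,-15,135
P07,pressure,L,28,100
P08,pressure,L,26,130
P09,pressure,L,-30,175
P10,pressure,L,-12,185
P11,pressure,L,5,190
P12,pressure,L,20,182
P13,pressure,L,33,170
P14,pressure,L,-15,235
P15,pressure,L,3,240
P16,pressure,L,20,228
T01,temperature,L,0,235
T02,temperature,L,-25,175
T03,temperature,L,0,185
T04,temperature,L,25,172
T05,temperature,L,0,120
T06,temperature,L,-15,35
T07,temperature,L,15,35
T08,temperature,L,0,60
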