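SketchEl!(6,4)
N=0.0000,0.0000;1,0
H=0.7071,0.7071;0,0,i:2
H=-0.7071,0.7071;0,0,i:2
H=-0.7071,-0.7071;0,0,i:2
H=0.7071,-0.7071;0,0,i:2
Br=3.0000,0.0000;-1,0
1-2=1,0
1-3=1,0
1-4=1,0
1-5=1,0
!End
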