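SketchEl!(2,1)
Ph=0.0000,0.0000;0,0,a:SketchEl!(7\,7)\nC=0.0000\,1.5000;0\,0\nC=-1.2990\,0.7500;0\,0\nC=-1.2990\,-0.7500;0\,0\nC=0.0000\,-1.5000;0\,0\nC=1.2990\,-0.7500;0\,0\nC=1.2990\,0.7500;0\,0\n*=0.0000\,3.0000;0\,0\n1-2=2\,0\n2-3=1\,0\n3-4=2\,0\n4-5=1\,0\n5-6=2\,0\n6-1=1\,0\n7-1=1\,0\n!End\n
Br=1.5000,0.0000;0,0
1-2=1,0
!End
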