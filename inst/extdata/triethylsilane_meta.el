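SketchEl!(1,0)
Et3Si=0.0000,0.0000;0,0,a:SketchEl!(5\,4)\nSi=0.0000\,0.0000;0\,0\,h1\nEt=0.0000\,1.5000;0\,0\,a:SketchEl!(3\\\,2)\\n*=-1.5000\\\,0.0000;0\\\,0\\nC=0.0000\\\,0.0000;0\\\,0\\nC=0.7500\\\,1.2990;0\\\,0\\n1-2=1\\\,0\\n2-3=1\\\,0\\n!End\\n\nEt=-1.2990\,-0.7500;0\,0\,a:SketchEl!(3\\\,2)\\n*=-1.5000\\\,0.0000;0\\\,0\\nC=0.0000\\\,0.0000;0\\\,0\\nC=0.7500\\\,1.2990;0\\\,0\\n1-2=1\\\,0\\n2-3=1\\\,0\\n!End\\n\nEt=1.2990\,-0.7500;0\,0\,a:SketchEl!(3\\\,2)\\n*=-1.5000\\\,0.0000;0\\\,0\\nC=0.0000\\\,0.0000;0\\\,0\\nC=0.7500\\\,1.2990;0\\\,0\\n1-2=1\\\,0\\n2-3=1\\\,0\\n!End\\n\n*=0.0000\,-1.5000;0\,0\n1-2=1\,0\n1-3=1\,0\n1-4=1\,0\n5-1=1\,0\n!End\n
!End
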