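1.983	stim1	/Event/Category/Incidental, /Event/Label/Evt40, /Event/Description/Generated event number 1, /Attribute/Visual/Color/Red, /Item/Object/Furniture/Chair
3.08	stim2	/Event/Category/Environmental, /Event/Label/Evt26, /Event/Description/Generated event number 2, /Attribute/Duration/0.5 s
3.754	rt	/Event/Category/Incidental, /Event/Label/Evt43, /Event/Description/Generated event number 3
4.358	stim1	/Event/Category/Participant response, /Event/Label/Evt36, /Event/Description/Generated event number 4, /Sensory presentation/Visual, /Item/Object/Furniture/Chair
5.224	stim2	/Event/Category/Experimental stimulus, /Event/Label/Evt53, /Event/Description/Generated event number 5
6.912	stim1	/Event/Category/Experimental stimulus, /Event/Label/Evt31, /Event/Description/Generated event number 6, /Participant/Effect/Cognitive/Target
7.922	stim2	/Event/Category/Participant response, /Event/Label/Evt88, /Event/Description/Generated event number 7, /Item/2D shape/Ellipse/Circle
9.88	stim2	/Event/Category/Environmental, /Event/Label/Evt87, /Event/Description/Generated event number 8, /Attribute/Visual/Color/Red
10.629	square	/Event/Category/Experimental stimulus, /Event/Label/Evt80, /Event/Description/Generated event number 9, /Attribute/Duration/0.5 s, /Sensory presentation/Visual
11.817	rt	/Event/Category/Participant response, /Event/Label/Evt40, /Event/Description/Generated event number 10, /Item/2D shape/Ellipse/Circle
12.575	square	/Event/Category/Incidental, /Event/Label/Evt94, /Event/Description/Generated event number 11, /Item/Object/Furniture/Chair, /Sensory presentation/Visual
13.422	stim2	/Event/Category/Participant response, /Event/Label/Evt44, /Event/Description/Generated event number 12
15.081	stim1	/Event/Category/Experimental stimulus, /Event/Label/Evt18, /Event/Description/Generated event number 13
15.726	square	/Event/Category/Incidental, /Event/Label/Evt75, /Event/Description/Generated event number 14, /Item/Object/Furniture/Chair
16.906	rt	/Event/Category/Experimental stimulus, /Event/Label/Evt8, /Event/Description/Generated event number 15, /Item/Object/Furniture/Chair, /Item/2D shape/Ellipse/Circle
17.533	stim2	/Event/Category/Participant response, /Event/Label/Evt43, /Event/Description/Generated event number 16
18.874	stim2	/Event/Category/Participant response, /Event/Label/Evt88, /Event/Description/Generated event number 17
19.387	rt	/Event/Category/Environmental, /Event/Label/Evt18, /Event/Description/Generated event number 18, /Participant/Effect/Cognitive/Target, /Item/2D shape/Ellipse/Circle, /Item/Object/Furniture/Chair
21.366	stim1	/Event/Category/Environmental, /Event/Label/Evt95, /Event/Description/Generated event number 19, /Participant/Effect/Cognitive/Target, /Attribute/Duration/0.5 s, /Item/2D shape/Ellipse/Circle
22.341	rt	/Event/Category/Incidental, /Event/Label/Evt37, /Event/Description/Generated event number 20
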