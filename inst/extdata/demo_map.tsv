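square	/Event/Category/Experimental stimulus, /Event/Label/RedFixationCircle, /Event/Description/Displayed to user a red circle for fixation in center of the screen and a blue square on the left. User sees the red circle, (/Item/2D shape/Ellipse/Circle, /Attribute/Visual/Color/Red, /Attribute/Fixation point, /Attribute/Location/Screen/Center, /Sensory presentation/Visual/Rendering type/Screen/2D, /Participant/Effect/Visual), (/Item/2D shape/Rectangle/Square, /Attribute/Visual/Color/Blue, /Attribute/Location/Screen/Left, /Sensory presentation/Visual/Rendering type/Screen/2D)
rt	/Event/Category/Participant response, /Event/Label/rt, /Event/Description/Participant presses the response button, /Action/Type/Press
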