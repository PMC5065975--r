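red_circle	/Event/Category/Experimental stimulus, /Event/Label/RedFixationCircle, /Event/Description/Displayed to user a red circle for fixation in center of the screen and a blue square on the left. User sees the red circle, (/Item/2D shape/Ellipse/Circle, /Attribute/Visual/Color/Red, /Attribute/Fixation point, /Attribute/Location/Screen/Center, /Sensory presentation/Visual/Rendering type/Screen/2D, /Participant/Effect/Visual), (/Item/2D shape/Rectangle/Square, /Attribute/Visual/Color/Blue, /Attribute/Location/Screen/Left, /Sensory presentation/Visual/Rendering type/Screen/2D)
chair_target	/Event/Category/Experimental stimulus, /Event/Description/A picture chair is displayed on the screen, /Sensory presentation/Visual, /Participant/Effect/Visual, /Participant/Effect/Cognitive/Target, /Item/Object/Furniture/Chair
oddball_pair	/Participant/Effect/Cognitive/Oddball, /Attribute/Presentation fraction/0.1
man_ate_fish	(/Item/Object/Person ~ /Action/Type/Eat ~ /Item/Object/Animal/Fish)
car_perturb	(/Item/Object/Vehicle/Car ~ /Attribute/Vehicle Control/Perturb)
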