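!Version 2.0
'''Event''' [Something that happens at a moment or over an interval.]
* Category {childRequired, required} [The general category of the event.]
** Initial context
** Participant response
** Technical error
** Participant failure
** Environmental
** Experimental stimulus
** Experimental procedure
** Incidental
** Miscellaneous
** Experimental control
* Label {childRequired, required} [A short study-specific identifier for events of this type.]
** # {takesValue}
* Description {childRequired, recommended, unique} [A human-readable description of what the event represents.]
** # {takesValue}
'''Item''' {extensionAllowed} [A thing that can be presented or take part in an event.]
* ID {predicateType=property}
** # {isNumeric, takesValue}
* Group ID {predicateType=property}
** # {isNumeric, takesValue}
* 2D shape
** Ellipse
*** Circle
** Rectangle
*** Square
** Star
* Object {extensionAllowed}
** Person
** Animal
*** Fish
** Vehicle
*** Car
** Furniture
*** Chair
'''Sensory presentation''' [How an item reaches the participant's senses.]
* Visual {extensionAllowed}
** Rendering type
*** Screen
**** 2D
**** 3D
* Auditory
'''Attribute''' {extensionAllowed} [Descriptive modifiers, orthogonal to the items they describe.]
* Visual
** Color
*** Red
*** Blue
*** Green
* Fixation point
* Location
** Screen
*** Center
*** Left
*** Right
*** Top
*** Bottom
* Presentation fraction [Fraction of presented stimuli belonging to this class.]
** # {isNumeric, takesValue}
* Vehicle Control
** Perturb
** Brake
** Steer
* Onset
* Offset
* Duration
** # {isNumeric, takesValue, unitClass=time}
* Temporal rate
** # {isNumeric, takesValue, unitClass=frequency}
* Size
** Length
*** # {isNumeric, takesValue, unitClass=physicalLength}
* Angle
** # {isNumeric, takesValue, unitClass=angle}
'''Action''' [An action performed by a participant or item.]
* Type {extensionAllowed}
** Eat
** Walk
** Press
** Look
'''Participant''' [The participant, their role, state and the event's effect.]
* ID {default=1, predicateType=property}
** # {isNumeric, takesValue}
* Role
** Experimenter
** Subject
* Effect
** Visual
** Auditory
** Cognitive
*** Target
*** Oddball
*** Threat
*** Reward
**** # {takesValue, unitClass=currency}
* State {extensionAllowed}
** Attention
** Fatigue
'''Experiment context''' {extensionAllowed}
* Indoors
* Outdoors
'''Paradigm''' {extensionAllowed}
* Visual oddball
* N-back
* Driving
'''HED''' {extensionAllowed}
'''Custom''' {extensionAllowed}
!UnitClasses
* angle {default=radian}: degree, radian
* area {default=m^2}: m^2
* currency {default=$}: $
* frequency {default=Hz}: Hz
* jerk {default=m-per-s^3}: m-per-s^3
* physicalLength {default=m}: m, cm, mm
* time {default=s}: s, ms
* velocity {default=m-per-s}: m-per-s
* volume {default=m^3}: m^3
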