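menu,condition,choline,potassium,calcium,folate,magnesium,zinc,vitamin_d,vitamin_c,total
HUSS,as_given,83.4,100,100,100,100,100,69.2,100,94.0
HUSS,egg_substitution,95.1,100,100,100,100,100,75.2,100,96.3
DASH,as_given,79.6,100,100,100,100,100,55.4,100,91.8
DASH,egg_substitution,91.1,100,100,100,100,100,59.4,100,93.8
Harvard,as_given,88.6,100,48.4,100,100,93.9,65.1,100,87.0
Harvard,egg_substitution,98.3,100,48.4,100,100,94.1,63.0,100,88.0
HVEG,as_given,91.1,100,100,100,100,100,44.1,100,91.9
HVEG,egg_substitution,100,100,100,100,100,100,50.5,100,93.8
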