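menu,condition,mean_usd,sd_usd
HUSS,as_given,9.6,1.4
HUSS,egg_substitution,9.5,1.4
Harvard,as_given,6.4,1.3
Harvard,egg_substitution,6.2,1.3
DASH,as_given,6.1,0.7
DASH,egg_substitution,5.9,0.6
HVEG,as_given,6.8,2.0
HVEG,egg_substitution,6.8,1.9
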