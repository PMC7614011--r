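{"thorax":[-0.327090909090911,-0.217890909090911,12.3914848484848],"abdomen":[0.438649478207487,-0.219324739103747,-12.4068446899939],"heart":[5.06285178236397,3.37260787992495,11.2],"liver":[-5.6,2.8,-11.2]}
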