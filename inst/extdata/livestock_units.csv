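species,coefficient
cattle,1.0
buffalo,1.0
camel,1.1
horse,0.8
mule,0.6
donkey,0.5
sheep,0.15
goat,0.1
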