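position,photon_flux
top,18.1
top,18.2
top,18.3
top,18.1
top,18.2
top,18.3
top,18.1
top,18.2
top,18.3
top,18.1
top,18.2
top,18.3
top,18.1
top,18.2
top,18.3
bottom,2.6
bottom,2.7
bottom,2.8
bottom,2.6
bottom,2.7
bottom,2.8
bottom,2.6
bottom,2.7
bottom,2.8
bottom,2.6
bottom,2.7
bottom,2.8
bottom,2.6
bottom,2.7
bottom,2.8
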