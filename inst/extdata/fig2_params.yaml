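# Reference invasion scenario: farmer-led monostable wave into the
# hunter-gatherer state with a three-population coexistence wake.
a: 1
b: 1
s: 0.01
g: 0.15
w: 0.3
p: 1.1
q: 0.1
l: 800
d: 80
t_end: 450
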