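# two-node tandem patient-flow network: arrivals -> WAIT -> TRANSIT -> out
0 -> WAIT @ k0 [u_arrivals]
WAIT -> TRANSIT @ k1
TRANSIT -> 0 @ k2
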