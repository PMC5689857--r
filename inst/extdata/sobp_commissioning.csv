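# SOBP commissioning comparison for the three reference beams
# (one per configuration group): measured and simulated modulation
# widths (cm) and the absolute D90 / D20 depth differences (cm).
config,group,measured_width,simulated_width,d90_diff,d20_diff
1,large,19.78,20.02,0.04,0.14
13,deep,9.77,9.93,0.07,0.10
20,small,15.41,15.33,0.08,0.07
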