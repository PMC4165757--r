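# Invasive tungsten needle electrode, illustrative component values
type: needle
cEh: 0.0        # needle-hemocoel interface capacitance (F)
rEh: 1.0e+4     # needle-hemocoel interface resistance (ohm)
rBody: 4.0e+4   # hemocoel bulk resistance (ohm)
rLoad: 1.0e+8   # amplifier input resistance (ohm)
cLoad: 2.4e-9   # amplifier input capacitance (F)
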