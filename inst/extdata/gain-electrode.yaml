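# Noninvasive GaIn (eutectic gallium-indium) electrode, illustrative values
type: gain
rIp: 1.25e+6    # GaIn-puparium interface resistance (ohm)
cIp: 1.0e-9     # GaIn-puparium interface capacitance (F)
rSeries: 1.0e+6 # series DC resistance of the GaIn path (ohm)
rLoad: 1.0e+8   # amplifier input resistance (ohm)
cLoad: 2.4e-9   # amplifier input capacitance (F)
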