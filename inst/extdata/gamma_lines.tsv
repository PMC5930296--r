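# Principal gamma emissions of the supported therapy radionuclides.
# Only lines with emission probability > 1% are modeled.
# half_life_s: I131 8.03 d, Lu177 6.65 d, Re188 17.00 h
isotope	energy_kev	intensity	half_life_s
I131	284	0.061	693792
I131	364	0.815	693792
I131	637	0.072	693792
I131	723	0.018	693792
Lu177	113	0.062	574560
Lu177	208	0.104	574560
Re188	155	0.156	61200
Re188	478	0.011	61200
Re188	633	0.014	61200
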