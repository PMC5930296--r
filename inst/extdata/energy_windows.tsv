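# Acquisition energy-window settings (keV): 20% photopeak window (PW) with
# abutting lower (LSW) and upper (USW) scatter windows, per isotope.
# The "quebec" dialect narrows the Lu177 scatter windows to 21 keV.
isotope	dialect	window	lo_kev	hi_kev
I131	default	LSW	306	328
I131	default	PW	328	400
I131	default	USW	400	422
Lu177	default	LSW	146	187
Lu177	default	PW	187	229
Lu177	default	USW	229	270
Lu177	quebec	LSW	166	187
Lu177	quebec	PW	187	229
Lu177	quebec	USW	229	250
Re188	default	LSW	132	140
Re188	default	PW	140	171
Re188	default	USW	171	178
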