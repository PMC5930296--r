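# Mass attenuation coefficients for liquid water (cm^2/g), coherent scattering excluded
# density_g_cm3: 1
energy_kev	photoelectric	incoherent	total
30	1.169721e-01	1.997321e-01	3.167042e-01
40	4.794817e-02	1.934624e-01	2.414106e-01
50	2.400773e-02	1.877023e-01	2.117100e-01
60	1.364235e-02	1.823915e-01	1.960338e-01
80	5.592153e-03	1.729198e-01	1.785119e-01
100	2.800000e-03	1.647175e-01	1.675175e-01
120	1.591095e-03	1.575383e-01	1.591294e-01
140	9.866455e-04	1.511948e-01	1.521814e-01
160	6.522079e-04	1.455422e-01	1.461945e-01
180	4.527029e-04	1.404674e-01	1.409201e-01
200	3.265615e-04	1.358803e-01	1.362068e-01
230	2.117394e-04	1.297600e-01	1.299717e-01
260	1.447907e-04	1.243885e-01	1.245333e-01
300	9.291421e-05	1.181525e-01	1.182454e-01
350	5.761653e-05	1.115149e-01	1.115725e-01
400	3.808659e-05	1.058607e-01	1.058988e-01
450	2.643621e-05	1.009635e-01	1.009899e-01
500	1.907001e-05	9.666346e-02	9.668253e-02
560	1.342070e-05	9.213036e-02	9.214378e-02
640	8.871562e-06	8.691924e-02	8.692811e-02
720	6.157824e-06	8.244499e-02	8.245115e-02
800	4.442005e-06	7.854312e-02	7.854756e-02
900	3.083232e-06	7.429653e-02	7.429961e-02
1000	2.224119e-06	7.060327e-02	7.060550e-02
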