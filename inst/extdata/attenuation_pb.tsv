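# Mass attenuation coefficients for lead (cm^2/g), coherent scattering excluded
# density_g_cm3: 11.35
energy_kev	photoelectric	incoherent	total
30	5.406602e+00	1.423985e-01	5.549000e+00
40	5.411071e+00	1.379285e-01	5.549000e+00
50	5.415178e+00	1.338219e-01	5.549000e+00
60	5.418964e+00	1.300355e-01	5.549000e+00
80	5.425717e+00	1.232827e-01	5.549000e+00
100	5.431565e+00	1.174349e-01	5.549000e+00
120	3.405672e+00	1.123165e-01	3.517988e+00
140	2.285275e+00	1.077939e-01	2.393068e+00
160	1.617111e+00	1.037640e-01	1.720875e+00
180	1.191321e+00	1.001459e-01	1.291467e+00
200	9.021245e-01	9.687549e-02	9.990000e-01
230	6.381270e-01	9.251205e-02	7.306391e-01
260	4.666092e-01	8.868249e-02	5.552917e-01
300	3.188635e-01	8.423651e-02	4.031000e-01
350	2.205176e-01	7.950425e-02	3.000219e-01
400	1.568269e-01	7.547310e-02	2.323000e-01
450	1.196973e-01	7.198165e-02	1.916789e-01
500	9.248403e-02	6.891597e-02	1.614000e-01
560	7.187177e-02	6.568410e-02	1.375559e-01
640	5.362827e-02	6.196885e-02	1.155971e-01
720	4.173669e-02	5.877895e-02	1.005156e-01
800	3.270288e-02	5.599712e-02	8.870000e-02
900	2.536910e-02	5.296952e-02	7.833862e-02
1000	1.976358e-02	5.033642e-02	7.010000e-02
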