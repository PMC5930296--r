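# Mass attenuation coefficients for NaI(Tl) (cm^2/g), coherent scattering excluded
# density_g_cm3: 3.67
energy_kev	photoelectric	incoherent	total
30	3.778954e+01	1.536321e-01	3.794317e+01
40	1.718064e+01	1.488094e-01	1.732945e+01
50	9.321933e+00	1.443788e-01	9.466312e+00
60	5.656521e+00	1.402938e-01	5.796814e+00
80	2.571682e+00	1.330083e-01	2.704690e+00
100	1.395352e+00	1.266992e-01	1.522051e+00
120	8.466954e-01	1.211770e-01	9.678723e-01
140	5.550000e-01	1.162976e-01	6.712976e-01
160	3.849418e-01	1.119497e-01	4.968915e-01
180	2.787643e-01	1.080462e-01	3.868105e-01
200	2.088630e-01	1.045178e-01	3.133809e-01
230	1.424130e-01	9.981016e-02	2.422231e-01
260	1.017787e-01	9.567849e-02	1.974572e-01
300	6.876565e-02	9.088177e-02	1.596474e-01
350	4.507517e-02	8.577620e-02	1.308514e-01
400	3.126363e-02	8.142704e-02	1.126907e-01
450	2.264027e-02	7.766015e-02	1.003004e-01
500	1.696313e-02	7.435262e-02	9.131575e-02
560	1.243508e-02	7.086580e-02	8.330088e-02
640	8.624833e-03	6.685746e-02	7.548229e-02
720	6.245867e-03	6.341591e-02	6.966178e-02
800	4.679692e-03	6.041463e-02	6.509432e-02
900	3.388904e-03	5.714819e-02	6.053709e-02
1000	2.539123e-03	5.430737e-02	5.684650e-02
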