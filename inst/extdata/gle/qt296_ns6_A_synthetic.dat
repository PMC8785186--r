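# QT GLE drift matrix A, units fs^-1, Ns=6; synthetic set fitted with neaspec::fitQTParameters(temperature=296, ns=6, nuRange=c(100,4000), nNu=24, maxit=4000, seed=7); target T = 296 K
7.2383604250767355e-02 -2.7595550883267017e-01 0.0000000000000000e+00 4.3483361328802254e-02 0.0000000000000000e+00 1.4637766815899894e-01 0.0000000000000000e+00
6.1799928768025014e-01 9.6005897560926274e-03 1.3521735193221184e-02 0.0000000000000000e+00 0.0000000000000000e+00 0.0000000000000000e+00 0.0000000000000000e+00
0.0000000000000000e+00 -1.3521735193221184e-02 9.6005897560926274e-03 0.0000000000000000e+00 0.0000000000000000e+00 0.0000000000000000e+00 0.0000000000000000e+00
2.3264877787792917e-01 0.0000000000000000e+00 0.0000000000000000e+00 1.0389371405531737e-01 3.0552349819533065e-01 0.0000000000000000e+00 0.0000000000000000e+00
0.0000000000000000e+00 0.0000000000000000e+00 0.0000000000000000e+00 -3.0552349819533065e-01 1.0389371405531737e-01 0.0000000000000000e+00 0.0000000000000000e+00
1.3387418220009635e+00 0.0000000000000000e+00 0.0000000000000000e+00 0.0000000000000000e+00 0.0000000000000000e+00 1.6022372878557778e+00 1.8852186492828134e+00
0.0000000000000000e+00 0.0000000000000000e+00 0.0000000000000000e+00 0.0000000000000000e+00 0.0000000000000000e+00 -1.8852186492828134e+00 1.6022372878557778e+00
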