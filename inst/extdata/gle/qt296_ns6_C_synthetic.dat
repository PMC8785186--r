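# QT GLE stationary covariance C, units eV, Ns=6; companion of qt296_ns6_A_synthetic.dat
2.7165688553852832e-02 9.6686652103845395e-03 7.0472465445835866e-03 1.1040254648036957e-01 8.0001157121130553e-02 -2.7983177375599723e-02 -1.3246216965908297e-01
9.6686652103845395e-03 1.0434781713535007e-01 1.8140674675937191e-02 2.7975972235414170e-01 -2.6965952758698586e-01 -6.4418280965273800e-03 6.2711169505517639e-02
7.0472465445835866e-03 1.8140674675937191e-02 2.2700930363495214e-01 1.0374938359594960e-01 1.1898461855163335e-02 2.5446655794077617e-04 2.2572429105710619e-02
1.1040254648036957e-01 2.7975972235414170e-01 1.0374938359594960e-01 1.4529599766929517e+00 -8.8985404764225687e-02 -2.5129983939284506e-01 9.8996602187937210e-01
8.0001157121130553e-02 -2.6965952758698586e-01 1.1898461855163335e-02 -8.8985404764225687e-02 1.5340553957205305e+00 -3.5375856972249420e-01 2.1031230225791189e-01
-2.7983177375599723e-02 -6.4418280965273800e-03 2.5446655794077617e-04 -2.5129983939284506e-01 -3.5375856972249420e-01 1.8270708020934017e+00 9.4562069979832541e-01
-1.3246216965908297e-01 6.2711169505517639e-02 2.2572429105710619e-02 9.8996602187937210e-01 2.1031230225791189e-01 9.4562069979832541e-01 6.9103882559724923e+00
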