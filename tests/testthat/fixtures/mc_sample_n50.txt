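8.625260000000000149e-01
5.799900000000000055e-01
2.659221000000000057e+00
8.837120000000000530e-01
7.098780000000000090e-01
7.544950000000000268e-01
1.530887000000000109e+00
1.339579000000000075e+00
1.391226999999999991e+00
1.411505000000000010e+00
5.547336999999999740e+00
7.224319999999999631e-01
6.637870000000000159e-01
5.215149999999999508e-01
1.636865999999999932e+00
2.467432000000000070e+00
9.128730000000000455e-01
5.106220000000000203e-01
5.170660000000000256e-01
1.682825999999999933e+00
1.812311999999999923e+00
1.544227000000000016e+00
5.871889999999999610e-01
1.204096000000000055e+00
1.097844000000000042e+00
1.191187999999999914e+00
2.008007999999999793e+00
1.195872999999999964e+00
1.721387999999999918e+00
1.055550999999999906e+00
1.260232000000000019e+00
1.657035999999999953e+00
3.116970000000000018e-01
7.743459999999999788e-01
6.863979999999999526e-01
5.998339999999999783e-01
8.024270000000000014e-01
3.306707999999999981e+00
5.002410000000000467e-01
2.169773000000000174e+00
2.602019999999999889e-01
7.649780000000000468e-01
1.139059000000000044e+00
1.598360000000000003e+00
1.766467000000000009e+00
1.886414000000000035e+00
7.565549999999999775e-01
6.908159999999999856e-01
1.986512999999999973e+00
8.580919999999999659e-01
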