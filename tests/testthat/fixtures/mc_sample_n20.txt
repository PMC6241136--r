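1.276054999999999939e+00
4.351840000000000153e-01
1.822777000000000092e+00
2.122196999999999889e+00
2.099620000000000097e-01
3.528390000000000137e-01
1.107685000000000031e+00
7.764720000000000510e-01
9.866489999999999982e-01
5.053849999999999731e-01
2.020849999999999813e+00
1.863085000000000102e+00
1.054245000000000099e+00
2.464017000000000124e+00
1.453548000000000062e+00
5.028650000000000064e-01
1.343126999999999960e+00
4.643550000000000177e-01
2.019318999999999864e+00
9.608459999999999779e-01
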