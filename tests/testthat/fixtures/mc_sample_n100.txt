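3.603970000000000229e-01
4.038829999999999920e-01
4.792359999999999953e-01
1.488439999999999985e+00
1.120686000000000071e+00
1.737397000000000080e+00
7.104890000000000372e-01
1.135226000000000068e+00
1.649499999999999966e+00
7.807680000000000176e-01
1.441119000000000039e+00
5.888750000000000373e-01
7.479320000000000412e-01
7.368360000000000465e-01
3.841689999999999827e-01
1.476358000000000059e+00
6.869309999999999583e-01
1.010045000000000082e+00
1.469022999999999968e+00
1.429356999999999989e+00
1.702857999999999983e+00
9.242350000000000287e-01
7.127400000000000402e-01
9.382160000000000499e-01
2.592749999999999777e-01
3.142110000000000181e-01
3.470940000000000136e-01
4.503199999999999981e-01
1.376878999999999964e+00
4.846230000000000260e-01
7.389459999999999917e-01
2.827471000000000068e+00
7.520059999999999523e-01
1.804011000000000031e+00
4.738359999999999794e-01
8.484450000000000047e-01
4.676580000000000181e-01
7.624440000000000106e-01
1.958631999999999929e+00
2.511120000000000019e-01
1.415578999999999921e+00
1.209478000000000053e+00
6.216859999999999609e-01
3.144759999999999778e-01
1.059401000000000037e+00
6.546899999999999942e-01
1.204592000000000107e+00
1.017635000000000067e+00
3.601761999999999908e+00
8.257320000000000215e-01
4.409609999999999919e-01
1.154214999999999991e+00
1.192434999999999912e+00
2.966403000000000123e+00
1.950506000000000073e+00
1.330422999999999911e+00
3.224063000000000123e+00
3.863500000000000267e-01
5.994150000000000311e-01
4.765130000000000199e-01
7.320929999999999938e-01
3.324219999999999953e-01
1.662164999999999893e+00
8.371279999999999832e-01
3.083110000000000017e-01
4.437639999999999918e-01
1.285066999999999959e+00
1.955216999999999983e+00
4.940095999999999599e+00
1.028914999999999935e+01
1.393094999999999972e+00
4.531049999999999800e-01
1.816570000000000129e-01
1.238831999999999933e+00
5.218620000000000481e-01
7.172819999999999752e-01
6.128240000000000354e-01
8.934790000000000232e-01
2.346169999999999867e+00
1.133872999999999909e+00
8.808150000000000146e-01
4.366940000000000266e-01
2.619119999999999782e-01
6.777030000000000554e-01
9.578860000000000152e-01
4.113787000000000305e+00
1.109844000000000053e+00
2.195021000000000111e+00
6.706980000000000164e-01
3.875330000000000163e-01
4.620449999999999835e-01
5.597969999999999891e-01
5.489162999999999570e+00
5.183480000000000310e-01
1.955783999999999967e+00
4.856139999999999901e-01
2.106986000000000026e+00
1.360648000000000080e+00
8.822229999999999794e-01
9.679159999999999986e-01
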