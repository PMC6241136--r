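5.922479999999999967e-01
1.428833000000000020e+00
6.948999999999999622e-01
3.751289999999999902e-01
3.597489999999999855e-01
1.148055999999999965e+00
3.536979000000000095e+00
1.136544999999999916e+00
9.094539999999999846e-01
1.256915999999999922e+00
2.842833999999999861e+00
1.191848999999999936e+00
7.198290000000000521e-01
2.423058999999999852e+00
1.409175999999999984e+00
3.416459999999999830e+00
1.157875999999999905e+00
3.754709999999999992e-01
3.346979999999999955e-01
3.746201000000000114e+00
3.970661000000000218e+00
8.662210000000000187e-01
7.359820000000000251e-01
3.219272999999999829e+00
4.124519999999999853e-01
4.888100000000000223e-01
1.673071999999999893e+00
7.292899999999999938e-01
9.959109999999999907e-01
8.774330000000000185e-01
1.310043000000000069e+00
3.083254000000000161e+00
1.075158000000000058e+00
1.673891000000000018e+00
1.939529999999999865e-01
9.617750000000000465e-01
5.093680000000000430e-01
3.771729999999999805e-01
4.953350000000000253e-01
7.654440000000000133e-01
2.080737000000000059e+00
3.460699999999999887e-01
1.024807999999999941e+00
6.788629999999999942e-01
7.694039999999999768e-01
2.230456000000000216e+00
1.538014999999999910e+00
2.915141999999999900e+00
8.837289999999999868e-01
5.730659999999999643e-01
8.360330000000000261e-01
1.214093000000000089e+00
1.151723000000000052e+00
4.199959999999999805e-01
1.075077000000000060e+00
1.200312999999999963e+00
7.493075000000000152e+00
4.488307999999999964e+00
5.053039999999999754e-01
7.946079999999999810e-01
3.101329999999999920e-01
6.234009999999999829e-01
1.287218999999999891e+00
2.623955000000000037e+00
5.580720000000000125e-01
5.925519999999999676e-01
1.794550000000000034e-01
8.779789999999999539e-01
4.274439999999999906e-01
6.547169999999999934e-01
4.958469999999999822e-01
9.273630000000000484e-01
2.450769999999999893e-01
3.092400000000000149e-01
5.492577999999999960e+00
3.570289999999999853e-01
4.158510000000000262e-01
4.347195000000000142e+00
1.021700799999999987e+01
3.917019999999999946e-01
7.448299999999999921e-01
1.314221000000000084e+00
3.986676999999999804e+00
4.540779999999999816e-01
8.218299999999999494e-01
1.862408000000000063e+00
1.415966999999999976e+00
7.401330000000000409e-01
8.984729999999999661e-01
3.328990000000000005e-01
8.265139999999999709e-01
8.080669999999999797e-01
1.204104000000000063e+00
6.412980000000000347e-01
1.458240999999999898e+00
2.248295999999999850e+00
1.132405000000000106e+00
1.324989999999999890e+00
1.043441000000000063e+00
1.000067999999999957e+00
5.614419999999999966e-01
1.288135000000000030e+00
9.251219999999999999e-01
5.336311000000000249e+00
3.520785000000000053e+00
1.361623000000000028e+00
5.431089999999999529e-01
4.106850000000000223e-01
2.593255999999999784e+00
1.233924000000000021e+00
1.468313999999999897e+00
2.476669999999999983e-01
2.100028000000000006e+00
1.438406999999999991e+00
4.113359999999999794e-01
6.857649999999999579e-01
1.234879999999999978e+00
1.042866999999999988e+00
7.915699999999999958e-01
9.205440000000000289e-01
8.174369999999999692e-01
1.129810999999999899e+00
3.245254000000000083e+00
1.283070000000000044e-01
8.273890000000000411e-01
1.151666000000000079e+00
1.267182000000000031e+00
7.426490000000000036e-01
2.452739999999999920e-01
1.300041999999999920e+00
3.982381999999999866e+00
2.931449999999999889e-01
1.995835000000000026e+00
7.688800000000000079e-01
9.521239999999999704e-01
4.307110000000000105e-01
7.652409999999999490e-01
2.829318000000000222e+00
1.593804999999999916e+00
3.998219999999999885e+00
2.564925999999999817e+00
1.420870000000000077e+00
4.035569999999999879e+00
1.420763999999999916e+00
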