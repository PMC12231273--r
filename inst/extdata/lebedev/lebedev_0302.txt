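# Lebedev-Laikov quadrature orbit parameters, rule with 302 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 8.5459117251281483e-04
3 0.0000000000000000e+00 0.0000000000000000e+00 3.5991192850255709e-03
4 3.5156403455701052e-01 0.0000000000000000e+00 3.4497884243058830e-03
4 6.5663294102196124e-01 0.0000000000000000e+00 3.6048226014198819e-03
4 4.7290541325810048e-01 0.0000000000000000e+00 3.5767296617433670e-03
4 9.6183085226147838e-02 0.0000000000000000e+00 2.3521014136891642e-03
4 2.2196452362941779e-01 0.0000000000000000e+00 3.1089531224136749e-03
4 7.0117664160895454e-01 0.0000000000000000e+00 3.6500458076772551e-03
5 2.6441528870606629e-01 0.0000000000000000e+00 2.9823449631718041e-03
5 5.7189558918789607e-01 0.0000000000000000e+00 3.6008209322164601e-03
6 2.5100347517704652e-01 8.0007274940739515e-01 3.5715405542733870e-03
6 1.2335485325833270e-01 4.1277240831685308e-01 3.3923122050061698e-03
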