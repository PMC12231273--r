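# Lebedev-Laikov quadrature orbit parameters, rule with 170 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 5.5448429020373653e-03
2 0.0000000000000000e+00 0.0000000000000000e+00 6.0713327706707516e-03
3 0.0000000000000000e+00 0.0000000000000000e+00 6.3836747735150929e-03
4 2.5512526211141340e-01 0.0000000000000000e+00 5.1833875877477899e-03
4 6.7436014603627659e-01 0.0000000000000000e+00 6.3179290098137253e-03
4 4.3189106967194102e-01 0.0000000000000000e+00 6.2016700065890768e-03
5 2.6139313603359882e-01 0.0000000000000000e+00 5.4771433851373477e-03
6 4.9904531617960368e-01 1.4466307443251150e-01 5.9683839876811563e-03
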