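# Lebedev-Laikov quadrature orbit parameters, rule with 38 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 9.5238095238095247e-03
3 0.0000000000000000e+00 0.0000000000000000e+00 3.2142857142857140e-02
5 4.5970084338098310e-01 0.0000000000000000e+00 2.8571428571428571e-02
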