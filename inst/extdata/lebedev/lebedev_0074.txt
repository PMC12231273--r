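# Lebedev-Laikov quadrature orbit parameters, rule with 74 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 5.1306717973384638e-04
2 0.0000000000000000e+00 0.0000000000000000e+00 1.6604069565742039e-02
3 0.0000000000000000e+00 0.0000000000000000e+00 -2.9586038961038959e-02
4 4.8038446141526142e-01 0.0000000000000000e+00 2.6576207082159461e-02
5 3.2077264898077640e-01 0.0000000000000000e+00 1.6522170993715710e-02
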