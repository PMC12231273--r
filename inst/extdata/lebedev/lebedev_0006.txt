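# Lebedev-Laikov quadrature orbit parameters, rule with 6 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 1.6666666666666671e-01
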