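# Lebedev-Laikov quadrature orbit parameters, rule with 50 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 1.2698412698412700e-02
2 0.0000000000000000e+00 0.0000000000000000e+00 2.2574955908289240e-02
3 0.0000000000000000e+00 0.0000000000000000e+00 2.1093750000000001e-02
4 3.0151134457776357e-01 0.0000000000000000e+00 2.0173335537918870e-02
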