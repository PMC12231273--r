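# Lebedev-Laikov quadrature orbit parameters, rule with 110 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 3.8282704949371619e-03
3 0.0000000000000000e+00 0.0000000000000000e+00 9.7937375124875128e-03
4 1.8511563534473621e-01 0.0000000000000000e+00 8.2117372831911114e-03
4 6.9042104838229224e-01 0.0000000000000000e+00 9.9428148911781030e-03
4 3.9568947305594188e-01 0.0000000000000000e+00 9.5954713360709622e-03
5 4.7836902881215021e-01 0.0000000000000000e+00 9.6949963616630285e-03
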