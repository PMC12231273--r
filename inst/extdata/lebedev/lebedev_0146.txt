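# Lebedev-Laikov quadrature orbit parameters, rule with 146 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 5.9963136886213809e-04
2 0.0000000000000000e+00 0.0000000000000000e+00 7.3729997186207557e-03
3 0.0000000000000000e+00 0.0000000000000000e+00 7.2105153601444878e-03
4 6.7644104001142635e-01 0.0000000000000000e+00 7.1163554931175550e-03
4 4.1749612279654530e-01 0.0000000000000000e+00 6.7538294863144768e-03
4 1.5746766720390820e-01 0.0000000000000000e+00 7.5743941590540338e-03
6 1.4035538117131829e-01 4.4933283232695570e-01 6.9910873533032616e-03
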