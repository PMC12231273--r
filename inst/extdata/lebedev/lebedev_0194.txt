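# Lebedev-Laikov quadrature orbit parameters, rule with 194 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 1.7823404472446110e-03
2 0.0000000000000000e+00 0.0000000000000000e+00 5.7169059499771017e-03
3 0.0000000000000000e+00 0.0000000000000000e+00 5.5733831788487382e-03
4 6.7129734426952259e-01 0.0000000000000000e+00 5.6087040825879972e-03
4 2.8924656275754390e-01 0.0000000000000000e+00 5.1582377118053833e-03
4 4.4469331787174371e-01 0.0000000000000000e+00 5.5187714672736143e-03
4 1.2993354476500671e-01 0.0000000000000000e+00 4.1067770281693937e-03
5 3.4577021976112832e-01 0.0000000000000000e+00 5.0518460646148079e-03
6 1.5904171053835300e-01 8.3603601548245887e-01 5.5302489162330944e-03
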