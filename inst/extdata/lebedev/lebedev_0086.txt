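# Lebedev-Laikov quadrature orbit parameters, rule with 86 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 1.1544011544011541e-02
3 0.0000000000000000e+00 0.0000000000000000e+00 1.1943909085856280e-02
4 3.6960284645415020e-01 0.0000000000000000e+00 1.1110555710603400e-02
4 6.9435400660266644e-01 0.0000000000000000e+00 1.1876501294537141e-02
5 3.7424303909034118e-01 0.0000000000000000e+00 1.1812303746904481e-02
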