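# Lebedev-Laikov quadrature orbit parameters, rule with 230 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 -5.5226399197273249e-02
3 0.0000000000000000e+00 0.0000000000000000e+00 4.4502746074452258e-03
4 4.4920446873976111e-01 0.0000000000000000e+00 4.4968410679214043e-03
4 2.5204194902102012e-01 0.0000000000000000e+00 5.0491534504787496e-03
4 6.9819066584472422e-01 0.0000000000000000e+00 3.9764080180518828e-03
4 6.5874052434609598e-01 0.0000000000000000e+00 4.4014006503810144e-03
4 4.0385440500976602e-02 0.0000000000000000e+00 1.7245443505444009e-02
5 5.8238423097155845e-01 0.0000000000000000e+00 4.2310830953573427e-03
5 3.5458773905186880e-01 0.0000000000000000e+00 5.1980698640643986e-03
6 2.2721818089981871e-01 4.8646615358866468e-01 4.6957209725688826e-03
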