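# Lebedev-Laikov quadrature orbit parameters, rule with 266 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 -1.3137691273269519e-03
2 0.0000000000000000e+00 0.0000000000000000e+00 -2.5227287048593360e-03
3 0.0000000000000000e+00 0.0000000000000000e+00 4.1868538817005831e-03
4 7.0393733915854750e-01 0.0000000000000000e+00 5.3151679778108852e-03
4 1.0125262485724140e-01 0.0000000000000000e+00 4.0471423770862191e-03
4 4.6474487264205389e-01 0.0000000000000000e+00 4.1124823944069903e-03
4 3.2774206549716289e-01 0.0000000000000000e+00 3.5955848997587820e-03
4 6.6203386636999739e-01 0.0000000000000000e+00 4.2561313514281581e-03
5 8.5065080835203988e-01 0.0000000000000000e+00 4.2295827006472398e-03
6 3.2334845426928988e-01 1.1531120110097010e-01 4.0809142257805051e-03
6 2.3147901587126010e-01 5.2449392409223650e-01 4.0714675938309641e-03
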