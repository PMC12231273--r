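# Lebedev-Laikov quadrature orbit parameters, rule with 350 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 3.0067967494539359e-03
3 0.0000000000000000e+00 0.0000000000000000e+00 3.0506277456507709e-03
4 7.0689654639123156e-01 0.0000000000000000e+00 1.6211046002889910e-03
4 4.7946826257120251e-01 0.0000000000000000e+00 3.0057014849017519e-03
4 1.9275331548780189e-01 0.0000000000000000e+00 2.9909925296537740e-03
4 6.9303579613271227e-01 0.0000000000000000e+00 2.9821706441075951e-03
4 3.6083021155200912e-01 0.0000000000000000e+00 2.7215642373109921e-03
4 6.4984861614961686e-01 0.0000000000000000e+00 3.0335137958111412e-03
5 1.9329450132303391e-01 0.0000000000000000e+00 3.0079495552185328e-03
5 3.8004949198993032e-01 0.0000000000000000e+00 2.8819646030553070e-03
6 2.8995588254995741e-01 7.9345378565823155e-01 2.9583576265356962e-03
6 9.6841214551039570e-02 8.2808015066868623e-01 3.0360200264070878e-03
6 1.8334346470416590e-01 9.0746582653051266e-01 2.8321874039263029e-03
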