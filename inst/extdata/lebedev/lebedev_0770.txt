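# Lebedev-Laikov quadrature orbit parameters, rule with 770 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 2.1929420881811840e-04
2 0.0000000000000000e+00 0.0000000000000000e+00 1.4364336173190799e-03
3 0.0000000000000000e+00 0.0000000000000000e+00 1.4219403443358771e-03
4 5.0872044105023599e-02 0.0000000000000000e+00 6.7981235110505021e-04
4 1.2281987901788310e-01 0.0000000000000000e+00 9.9131842352949114e-04
4 2.0268908144087860e-01 0.0000000000000000e+00 1.1802078332389489e-03
4 2.8477451564642942e-01 0.0000000000000000e+00 1.2965996020809210e-03
4 3.6567190789780257e-01 0.0000000000000000e+00 1.3658714274283161e-03
4 4.4282648867134689e-01 0.0000000000000000e+00 1.4029886047753251e-03
4 5.1406196272497351e-01 0.0000000000000000e+00 1.4186455635956090e-03
4 6.3064012191668029e-01 0.0000000000000000e+00 1.4213767418516619e-03
4 6.7168833320226118e-01 0.0000000000000000e+00 1.4239964754909620e-03
4 6.9797926853368808e-01 0.0000000000000000e+00 1.4315540421785671e-03
5 1.4468656741953090e-01 0.0000000000000000e+00 9.2544014998653678e-04
5 3.3902634754112160e-01 0.0000000000000000e+00 1.2502399950535090e-03
5 5.3358046512635060e-01 0.0000000000000000e+00 1.3943658433292301e-03
6 6.9440243933494128e-02 2.3551878942423260e-01 1.1270890946717489e-03
6 2.2690041095294600e-01 4.1021824740457302e-01 1.3457537609106701e-03
6 8.0255746077753390e-02 6.2143024174816053e-01 1.4249572833167829e-03
6 1.4679995278965721e-01 3.2452843457173941e-01 1.2615233412377499e-03
6 1.5715077698247271e-01 5.2244821896966298e-01 1.3925471060526960e-03
6 2.3657029931572460e-01 6.0175466340895578e-01 1.4187616778776561e-03
6 7.7148158667657327e-02 4.3465755161411629e-01 1.3383666844795541e-03
6 3.0629366662107299e-01 4.9088265890376159e-01 1.3937008626761309e-03
6 3.8224773795247868e-01 5.6487681490995001e-01 1.4159147574669319e-03
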