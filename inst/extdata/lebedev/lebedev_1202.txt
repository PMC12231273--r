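# Lebedev-Laikov quadrature orbit parameters, rule with 1202 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 1.1051892332675720e-04
2 0.0000000000000000e+00 0.0000000000000000e+00 9.2052327380907407e-04
3 0.0000000000000000e+00 0.0000000000000000e+00 9.1331597864435614e-04
4 3.7126364496570891e-02 0.0000000000000000e+00 3.6904218980178988e-04
4 9.1400604122622228e-02 0.0000000000000000e+00 5.6039909286806605e-04
4 1.5310778524699059e-01 0.0000000000000000e+00 6.8652976292826089e-04
4 2.1809288916606120e-01 0.0000000000000000e+00 7.7203385511456302e-04
4 2.8398745322001751e-01 0.0000000000000000e+00 8.3015459588947952e-04
4 3.4911776009637641e-01 0.0000000000000000e+00 8.6866925501796277e-04
4 4.1214314614443093e-01 0.0000000000000000e+00 8.9270762858468904e-04
4 4.7189936271491267e-01 0.0000000000000000e+00 9.0608202385682190e-04
4 5.2731454528423372e-01 0.0000000000000000e+00 9.1197772549408669e-04
4 6.2094753324440188e-01 0.0000000000000000e+00 9.1287201386041814e-04
4 6.5697227118572910e-01 0.0000000000000000e+00 9.1307149356917349e-04
4 6.8417883090701426e-01 0.0000000000000000e+00 9.1528737845541163e-04
4 7.0126043301236307e-01 0.0000000000000000e+00 9.1874362743216544e-04
5 1.0723822154781661e-01 0.0000000000000000e+00 5.1769773129656943e-04
5 2.5820689594969681e-01 0.0000000000000000e+00 7.3311436821014173e-04
5 4.1727529553067172e-01 0.0000000000000000e+00 8.4632328363799282e-04
5 5.7003669117925027e-01 0.0000000000000000e+00 9.0311226942539917e-04
6 9.8279860182639467e-01 1.7717740226153250e-01 6.4857784531632573e-04
6 9.6242492303262284e-01 2.4757164634262879e-01 7.4350309109823688e-04
6 9.4020079941288115e-01 3.3546162890664888e-01 7.9985278918390538e-04
6 9.3208220401432018e-01 3.1736152466119771e-01 8.1017314974680184e-04
6 9.0436741993932990e-01 4.0902684270853568e-01 8.4833895745943305e-04
6 8.9124075600747465e-01 3.8542911506692240e-01 8.5562992573118117e-04
6 8.6764356284627075e-01 4.9322211848512848e-01 8.8032086797382603e-04
6 8.5819799860416190e-01 4.7853206759224348e-01 8.8110481824257196e-04
6 8.3967536240498564e-01 4.5074225931570638e-01 8.8502823412654438e-04
6 8.1652885640221884e-01 5.6321230207620998e-01 9.0213422990406526e-04
6 8.0154693707835289e-01 5.4343035696939002e-01 9.0100916771050860e-04
6 7.7735630690703506e-01 5.1235184864198713e-01 9.0226929384269153e-04
6 7.6616212139003936e-01 6.3942796347491015e-01 9.1580161746934654e-04
6 7.5535841435335105e-01 6.2698055090243920e-01 9.1315780031894355e-04
6 7.3443057575595028e-01 6.0311616930963097e-01 9.1078135794827046e-04
6 7.0438371840217651e-01 5.6937024984684415e-01 9.1057602589701258e-04
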