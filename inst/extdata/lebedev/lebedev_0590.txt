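# Lebedev-Laikov quadrature orbit parameters, rule with 590 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 3.0951212953061872e-04
3 0.0000000000000000e+00 0.0000000000000000e+00 1.8523796985974890e-03
4 7.0409549382274694e-01 0.0000000000000000e+00 1.8717906392777439e-03
4 6.8077440664552435e-01 0.0000000000000000e+00 1.8588125854383170e-03
4 6.3725469392587519e-01 0.0000000000000000e+00 1.8520288282962130e-03
4 5.0444197078003583e-01 0.0000000000000000e+00 1.8467159561512420e-03
4 4.2157617840109668e-01 0.0000000000000000e+00 1.8184717781627689e-03
4 3.3179207364721230e-01 0.0000000000000000e+00 1.7495646572811541e-03
4 2.3847367014218870e-01 0.0000000000000000e+00 1.6172106472544111e-03
4 1.4590364491577629e-01 0.0000000000000000e+00 1.3847372348516919e-03
4 6.0950341155071960e-02 0.0000000000000000e+00 9.7643311650510501e-04
5 6.1168434420098761e-01 0.0000000000000000e+00 1.8571611967740779e-03
5 3.9647553481998582e-01 0.0000000000000000e+00 1.7051539963958641e-03
5 1.7247820099077241e-01 0.0000000000000000e+00 1.3003216858860479e-03
6 5.6102638086220602e-01 3.5182809277335192e-01 1.8428664729052860e-03
6 4.7423928425519801e-01 2.6347166559379498e-01 1.8026589343774510e-03
6 5.9841264978853803e-01 1.8166408403602091e-01 1.8498305604436600e-03
6 3.7910354076955632e-01 1.7207952256568779e-01 1.7139045071067091e-03
6 2.7786731905862438e-01 8.2130215819325114e-02 1.5552136033968079e-03
6 5.0335642710751172e-01 8.9992058420748755e-02 1.8022391280085250e-03
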