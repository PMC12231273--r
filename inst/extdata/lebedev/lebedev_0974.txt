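# Lebedev-Laikov quadrature orbit parameters, rule with 974 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 1.4382941905274310e-04
3 0.0000000000000000e+00 0.0000000000000000e+00 1.1257722882870040e-03
4 4.2929635453413467e-02 0.0000000000000000e+00 4.9480293419492413e-04
4 1.0514268540864040e-01 0.0000000000000000e+00 7.3579901091254700e-04
4 1.7500248676230870e-01 0.0000000000000000e+00 8.8891327713043835e-04
4 2.4776533796502570e-01 0.0000000000000000e+00 9.8883478389214354e-04
4 3.2065671239559568e-01 0.0000000000000000e+00 1.0532996817094709e-03
4 3.9165207498499832e-01 0.0000000000000000e+00 1.0927788070145780e-03
4 4.5908258741876240e-01 0.0000000000000000e+00 1.1143893940632271e-03
4 5.2145638884158607e-01 0.0000000000000000e+00 1.1237247880515550e-03
4 6.2531702446541992e-01 0.0000000000000000e+00 1.1252393252438140e-03
4 6.6379267445231704e-01 0.0000000000000000e+00 1.1261532718159050e-03
4 6.9104103984983012e-01 0.0000000000000000e+00 1.1302869311238411e-03
4 7.0529070074577604e-01 0.0000000000000000e+00 1.1349865343639549e-03
5 1.2366867626579900e-01 0.0000000000000000e+00 6.8233679271099306e-04
5 2.9407771144683870e-01 0.0000000000000000e+00 9.4541581604470958e-04
5 4.6977538492076493e-01 0.0000000000000000e+00 1.0744299753856789e-03
5 6.3345632411395669e-01 0.0000000000000000e+00 1.1293000865691320e-03
6 5.9740486141813418e-02 2.0291287527775231e-01 8.4368845009019536e-04
6 1.3757604084736361e-01 4.6026219424840542e-01 1.0752557204488850e-03
6 3.3910165263362863e-01 5.0306739996620364e-01 1.1085772368644620e-03
6 1.2716751914398200e-01 2.8176064224421338e-01 9.5664753237833567e-04
6 2.6931207404135121e-01 4.3315612917201568e-01 1.0806632507173910e-03
6 1.4197864526019180e-01 6.2561673585808142e-01 1.1267971311962951e-03
6 6.7092846007382551e-02 3.7983952168591573e-01 1.0225687153580609e-03
6 7.0577381832561722e-02 5.5175054214235197e-01 1.1089602677131080e-03
6 2.7838884778821549e-01 6.0296191561591872e-01 1.1227906534357660e-03
6 1.9795789389174070e-01 3.5896063295890962e-01 1.0324018471174600e-03
6 2.0873070611032740e-01 5.3486664381354765e-01 1.1072493822838539e-03
6 4.0551221378728358e-01 5.6749975460743729e-01 1.1217800485199721e-03
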