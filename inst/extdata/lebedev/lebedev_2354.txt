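# Lebedev-Laikov quadrature orbit parameters, rule with 2354 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 3.9226162706652920e-05
2 0.0000000000000000e+00 0.0000000000000000e+00 4.7038317508544240e-04
3 0.0000000000000000e+00 0.0000000000000000e+00 4.6782028012821362e-04
4 2.2900246465305890e-02 0.0000000000000000e+00 1.4378322289799000e-04
4 5.7790866522712842e-02 0.0000000000000000e+00 2.3035724935776441e-04
4 9.8631035763759839e-02 0.0000000000000000e+00 2.9331107524474542e-04
4 1.4281557929821850e-01 0.0000000000000000e+00 3.4029059983598382e-04
4 1.8889781166014630e-01 0.0000000000000000e+00 3.7591384668703718e-04
4 2.3590916829702099e-01 0.0000000000000000e+00 4.0306384478997978e-04
4 2.8312288337061708e-01 0.0000000000000000e+00 4.2365914322422112e-04
4 3.2994958579666928e-01 0.0000000000000000e+00 4.3905226569467459e-04
4 3.7588408026607961e-01 0.0000000000000000e+00 4.5025234666262471e-04
4 4.2047518310094800e-01 0.0000000000000000e+00 4.5805777277835411e-04
4 4.6330685187510512e-01 0.0000000000000000e+00 4.6313916166158988e-04
4 5.0398494745073130e-01 0.0000000000000000e+00 4.6609289536986759e-04
4 5.4212657934407471e-01 0.0000000000000000e+00 4.6747518079369530e-04
4 6.0926602305573097e-01 0.0000000000000000e+00 4.6764149039329198e-04
4 6.3746542049848687e-01 0.0000000000000000e+00 4.6740864923478702e-04
4 6.6151364726098916e-01 0.0000000000000000e+00 4.6749285394832071e-04
4 6.8094872859581268e-01 0.0000000000000000e+00 4.6807489796864472e-04
4 6.9529800216651960e-01 0.0000000000000000e+00 4.6904498063890401e-04
4 7.0412454976953998e-01 0.0000000000000000e+00 4.6998770758608179e-04
5 6.7440330883060645e-02 0.0000000000000000e+00 2.0999422810691760e-04
5 1.6786844853341659e-01 0.0000000000000000e+00 3.1722691507128040e-04
5 2.7935590495396129e-01 0.0000000000000000e+00 3.8320513585465230e-04
5 3.9352642180576392e-01 0.0000000000000000e+00 4.2521938181469852e-04
5 5.0526292682325580e-01 0.0000000000000000e+00 4.5138079637549997e-04
5 6.1079053154375307e-01 0.0000000000000000e+00 4.6577974691141779e-04
6 1.1350810398435240e-01 3.3319548846625878e-02 2.7333628005228361e-04
6 1.6128666260993779e-01 7.2471674654365381e-02 3.2354853684635589e-04
6 2.1007865501682049e-01 1.1515391108497450e-01 3.6249087260134527e-04
6 2.5922820094599419e-01 1.5994910971436771e-01 3.9255400707128278e-04
6 3.0817405613202031e-01 2.0586999560280270e-01 4.1561297811162348e-04
6 3.5642897815781638e-01 2.5216249535029112e-01 4.3306449846232631e-04
6 4.0355872882407029e-01 2.9820907857976742e-01 4.4596777259213119e-04
6 4.4916711963739031e-01 3.4347620872357332e-01 4.5515930044567952e-04
6 4.9288547829174889e-01 3.8748313572034371e-01 4.6133414627499178e-04
6 5.3436467919589881e-01 4.2978148217469259e-01 4.6510196182698057e-04
6 5.7326832165309904e-01 4.6994022609435371e-01 4.6702495361006252e-04
6 2.2141315832189859e-01 3.8736020406438948e-02 3.5495555764417081e-04
6 2.7417965047500709e-01 8.0894962569020123e-02 3.8561082452490098e-04
6 3.2597974391494849e-01 1.2517321776208720e-01 4.0986228457568820e-04
6 3.7654411488268907e-01 1.7062602864031851e-01 4.2863286042689501e-04
6 4.2557735745305580e-01 2.1651151473004079e-01 4.4278021989939452e-04
6 4.7277951170584298e-01 2.6220898122252589e-01 4.5304735114885607e-04
6 5.1785468958190117e-01 3.0717214312962010e-01 4.6008054757031383e-04
6 5.6051411920974603e-01 3.5089989988011377e-01 4.6445990599580168e-04
6 6.0047633193525118e-01 3.9291608761669311e-01 4.6672744557125080e-04
6 3.3528426349469492e-01 4.2025634572880187e-02 4.0693605180203558e-04
6 3.8919716298146700e-01 8.6143097588708500e-02 4.2604428199191950e-04
6 4.4098755655422811e-01 1.3145008793800009e-01 4.4086785080290632e-04
6 4.9048930585924838e-01 1.7721896573838589e-01 4.5187481155485972e-04
6 5.3750561387695495e-01 2.2282771100502941e-01 4.5955648753751163e-04
6 5.8182557086699693e-01 2.6771799350143860e-01 4.6439887743158462e-04
6 6.2323348581449589e-01 3.1136750355441650e-01 4.6688274916469459e-04
6 4.4894853544920582e-01 4.4091623783681741e-02 4.4005418237419729e-04
6 5.0151368759331505e-01 8.9390099177484889e-02 4.5145128901937968e-04
6 5.5113005505126234e-01 1.3518060293833650e-01 4.5961986273475492e-04
6 5.9767204098579996e-01 1.8083703550531960e-01 4.6486590168017808e-04
6 6.4099563789893543e-01 2.2578521923016021e-01 4.6755020171576731e-04
6 5.5812223308275144e-01 4.5321734216371597e-02 4.5984944764555232e-04
6 6.0747059841616946e-01 9.1174880318403137e-02 4.6549169551520479e-04
6 6.5322725373790325e-01 1.3692942131401550e-01 4.6847097795051372e-04
6 6.5947614945004873e-01 4.5899014872755828e-02 4.6914455391069862e-04
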