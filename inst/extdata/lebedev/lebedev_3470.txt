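# Lebedev-Laikov quadrature orbit parameters, rule with 3470 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 2.0403827308263299e-05
3 0.0000000000000000e+00 0.0000000000000000e+00 3.1781497038895439e-04
4 1.7214208329062331e-02 0.0000000000000000e+00 8.2881151280761106e-05
4 4.4088753749817702e-02 0.0000000000000000e+00 1.3608831925229539e-04
4 7.5946808138786806e-02 0.0000000000000000e+00 1.7668544545426621e-04
4 1.1083353592047990e-01 0.0000000000000000e+00 2.0831531612301531e-04
4 1.4765170543885670e-01 0.0000000000000000e+00 2.3332795446571580e-04
4 1.8567318708606151e-01 0.0000000000000000e+00 2.5328095399302470e-04
4 2.2436340994288209e-01 0.0000000000000000e+00 2.6924721842111579e-04
4 2.6330068816627272e-01 0.0000000000000000e+00 2.8199499468118847e-04
4 3.0213409049162832e-01 0.0000000000000000e+00 2.9209535939730302e-04
4 3.4055940480300889e-01 0.0000000000000000e+00 2.9998897829483523e-04
4 3.7830444340073721e-01 0.0000000000000000e+00 3.0602921204969018e-04
4 4.1511947674079103e-01 0.0000000000000000e+00 3.1051091675221918e-04
4 4.5077057664432568e-01 0.0000000000000000e+00 3.1369023875503119e-04
4 4.8503460565731871e-01 0.0000000000000000e+00 3.1579846524546320e-04
4 5.1769508177924695e-01 0.0000000000000000e+00 3.1705165184254218e-04
4 5.4853842408209885e-01 0.0000000000000000e+00 3.1765684256337550e-04
4 6.0391172389433079e-01 0.0000000000000000e+00 3.1771984112070618e-04
4 6.2799566555731134e-01 0.0000000000000000e+00 3.1755194923947328e-04
4 6.4936361695689515e-01 0.0000000000000000e+00 3.1746549526347559e-04
4 6.6776441177045043e-01 0.0000000000000000e+00 3.1756764154676541e-04
4 6.8293685721156239e-01 0.0000000000000000e+00 3.1789234178354099e-04
4 6.9461958181841210e-01 0.0000000000000000e+00 3.1837882875319088e-04
4 7.0257115420570260e-01 0.0000000000000000e+00 3.1887551519188068e-04
4 7.0660047671401194e-01 0.0000000000000000e+00 3.1919168893138490e-04
5 5.1325376899460623e-02 0.0000000000000000e+00 1.2317796117445080e-04
5 1.2979946613312249e-01 0.0000000000000000e+00 1.9246613738398800e-04
5 2.1888520494013070e-01 0.0000000000000000e+00 2.3808818674034239e-04
5 3.1231748249034569e-01 0.0000000000000000e+00 2.6931006630378850e-04
5 4.0640376207381951e-01 0.0000000000000000e+00 2.9086733828343657e-04
5 4.9849583969447819e-01 0.0000000000000000e+00 3.0539146193815349e-04
5 5.8649750460213645e-01 0.0000000000000000e+00 3.1439166841477770e-04
5 6.6867116345801747e-01 0.0000000000000000e+00 3.1870422440553631e-04
6 8.7157387808359493e-02 2.5571752333675781e-02 1.6352195358697899e-04
6 1.2483831231340070e-01 5.6048233833766808e-02 1.9681099176960701e-04
6 1.6380626933833781e-01 8.9685686019007643e-02 2.2367543422499741e-04
6 2.0355862033731759e-01 1.2540866519762789e-01 2.4531866870171809e-04
6 2.4367989752937741e-01 1.6247801501620121e-01 2.6275517915805410e-04
6 2.8382075077738061e-01 2.0034223426832079e-01 2.7676548601522199e-04
6 3.2367875022176917e-01 2.3856280262552629e-01 2.8794670277658950e-04
6 3.6298495548406912e-01 2.7677311487835782e-01 2.9676399189187020e-04
6 4.0149480819920869e-01 3.1465423082453092e-01 3.0359006846603510e-04
6 4.3898183792602252e-01 3.5191964158950878e-01 3.0873382372983082e-04
6 4.7523311436743770e-01 3.8830509840236538e-01 3.1246088388601671e-04
6 5.1004573183740176e-01 4.2356134239086490e-01 3.1500842942267432e-04
6 5.4322383889548675e-01 4.5744847171962200e-01 3.1659583985984018e-04
6 5.7457586850724418e-01 4.8973116392555238e-01 3.1743204409573719e-04
6 1.7239814375928089e-01 3.0106305978811049e-02 2.1821889098125991e-04
6 2.1495532578445969e-01 6.3260315542046947e-02 2.3997279339214449e-04
6 2.5732560812474220e-01 9.8485669802586315e-02 2.5797961335146519e-04
6 2.9931637512381060e-01 1.3508359523842661e-01 2.7271140526235349e-04
6 3.4072380051480000e-01 1.7251840554421810e-01 2.8463276562813548e-04
6 3.8134549784832639e-01 2.1035592797307251e-01 2.9414911020513338e-04
6 4.2098481044233432e-01 2.4822787745548600e-01 3.0160494921361067e-04
6 4.5945196999963001e-01 2.8580995099828832e-01 3.0729497261756478e-04
6 4.9656401661859301e-01 3.2280756599154281e-01 3.1147681428864599e-04
6 5.3214416555715616e-01 3.5894599072041511e-01 3.1438236736662230e-04
6 5.6602084385821660e-01 3.9396300888643099e-01 3.1622697646615350e-04
6 5.9802643159643643e-01 4.2760299229490889e-01 3.1721646637598210e-04
6 2.6442158523507331e-01 3.3009394290725518e-02 2.5545753989674353e-04
6 3.0901137434430631e-01 6.8038876500785009e-02 2.7017040691356770e-04
6 3.5258710791978082e-01 1.0443261362067090e-01 2.8236934134689398e-04
6 3.9504180053540289e-01 1.4167515975176789e-01 2.9228984632142889e-04
6 4.3624756634301631e-01 1.7934086105048211e-01 3.0018290621624280e-04
6 4.7606618121458538e-01 2.1706307501757219e-01 3.0628908645429528e-04
6 5.1435510425121034e-01 2.5451451578158069e-01 3.1083282792647459e-04
6 5.5097090269355975e-01 2.9139401017066008e-01 3.1402431462012448e-04
6 5.8577110303294277e-01 3.2741699109107048e-01 3.1606380309771301e-04
6 6.1861499174043921e-01 3.6230813293172648e-01 3.1714628822062752e-04
6 3.5868945695570642e-01 3.4973543864500398e-02 2.8123884160317962e-04
6 4.0352666100194412e-01 7.1297367397570949e-02 2.9121375002880449e-04
6 4.4677753123325098e-01 1.0847586201931650e-01 2.9932412565022060e-04
6 4.8836383466085431e-01 1.4609156892417721e-01 3.0571017389838218e-04
6 5.2819083484346008e-01 1.8377908323699799e-01 3.1053193262514320e-04
6 5.6615426871493113e-01 2.2120753908740209e-01 3.1395655144281670e-04
6 6.0214501020314515e-01 2.5806828411609850e-01 3.1615430068063661e-04
6 6.3605207836100497e-01 2.9406563620941212e-01 3.1729859606132940e-04
6 4.5216110650871960e-01 3.6310553658670017e-02 2.9894003369014310e-04
6 4.9593656515609630e-01 7.3483184684843494e-02 3.0545558839476769e-04
6 5.3768158040382830e-01 1.1110876438126480e-01 3.1047649608077023e-04
6 5.7733144802437675e-01 1.4882260851454079e-01 3.1410158259776160e-04
6 6.1481132455750565e-01 1.8628922741351511e-01 3.1645206211598960e-04
6 6.5004074628423802e-01 2.2319097017144560e-01 3.1766523059122040e-04
6 5.4251514487072128e-01 3.7182013061189442e-02 3.1050971610239390e-04
6 5.8418605569079307e-01 7.4836163350673460e-02 3.1430141178905502e-04
6 6.2346321868514998e-01 1.1259908342661200e-01 3.1681728662872000e-04
6 6.6029345518488425e-01 1.5013038131576190e-01 3.1814018655709682e-04
6 6.2785739683751052e-01 3.7675599302457202e-02 3.1706636591560371e-04
6 6.6656117112645774e-01 7.5484433013601582e-02 3.1854479446255101e-04
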