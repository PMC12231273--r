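# Lebedev-Laikov quadrature orbit parameters, rule with 3074 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 2.5990959537547339e-05
2 0.0000000000000000e+00 0.0000000000000000e+00 3.6031340896875412e-04
3 0.0000000000000000e+00 0.0000000000000000e+00 3.5860679744124469e-04
4 1.8861085187233919e-02 0.0000000000000000e+00 9.8315284743858805e-05
4 4.8002172446253030e-02 0.0000000000000000e+00 1.6050231079544499e-04
4 8.2449220583972416e-02 0.0000000000000000e+00 2.0722001314640989e-04
4 1.2004083624840230e-01 0.0000000000000000e+00 2.4312976188141871e-04
4 1.5957735308099649e-01 0.0000000000000000e+00 2.7118190644967070e-04
4 2.0026359734340640e-01 0.0000000000000000e+00 2.9327620383211159e-04
4 2.4151275901399821e-01 0.0000000000000000e+00 3.1070325141973682e-04
4 2.8285841584584770e-01 0.0000000000000000e+00 3.2438080589212130e-04
4 3.2390910153381380e-01 0.0000000000000000e+00 3.3498990913740300e-04
4 3.6432250979621938e-01 0.0000000000000000e+00 3.4305806885052178e-04
4 4.0378970836918021e-01 0.0000000000000000e+00 3.4901241092903429e-04
4 4.4202475151941267e-01 0.0000000000000000e+00 3.5321489485619551e-04
4 4.7875725384649381e-01 0.0000000000000000e+00 3.5598626690628329e-04
4 5.1372652512752337e-01 0.0000000000000000e+00 3.5762243175514112e-04
4 5.4667640566546105e-01 0.0000000000000000e+00 3.5840505330860759e-04
4 6.0548594208135353e-01 0.0000000000000000e+00 3.5849035813732242e-04
4 6.3081067017645620e-01 0.0000000000000000e+00 3.5829918790405860e-04
4 6.5303692301795835e-01 0.0000000000000000e+00 3.5823711879631249e-04
4 6.7186095246111577e-01 0.0000000000000000e+00 3.5843536311223499e-04
4 6.8696764998940130e-01 0.0000000000000000e+00 3.5891201665177850e-04
4 6.9804670772407484e-01 0.0000000000000000e+00 3.5954457045316008e-04
4 7.0482417212505222e-01 0.0000000000000000e+00 3.6009435571110742e-04
5 5.5911052220582319e-02 0.0000000000000000e+00 1.4564470967420390e-04
5 1.4073840785139161e-01 0.0000000000000000e+00 2.2523701882837821e-04
5 2.3640354389763091e-01 0.0000000000000000e+00 2.7661354434748971e-04
5 3.3606027378181702e-01 0.0000000000000000e+00 3.1107294915008510e-04
5 4.3562926300546650e-01 0.0000000000000000e+00 3.3425067123033913e-04
5 5.3215694152561743e-01 0.0000000000000000e+00 3.4919818340268600e-04
5 6.2329563050405545e-01 0.0000000000000000e+00 3.5760036043489321e-04
6 9.4698700868384694e-02 2.7787483873094699e-02 1.9219213057885639e-04
6 1.3531703005681411e-01 6.0765698786283642e-02 2.3014582164956321e-04
6 1.7716794817260770e-01 9.7030727627110402e-02 2.6042485495228929e-04
6 2.1970666642317510e-01 1.3541124585247619e-01 2.8452754258706970e-04
6 2.6247835573749267e-01 1.7509964797440999e-01 3.0368708979748398e-04
6 3.0509695212144422e-01 2.1548969074498020e-01 3.1884148322980658e-04
6 3.4722526371960211e-01 2.5609546257401522e-01 3.3070464147220893e-04
6 3.8856102190263597e-01 2.9650700506240962e-01 3.3983309690313601e-04
6 4.2882737760627648e-01 3.3636414887344968e-01 3.4667578997053729e-04
6 4.6776624713029480e-01 3.7534000298367881e-01 3.5160959232300538e-04
6 5.0513335895533595e-01 4.1312975221442860e-01 3.5496451840484860e-04
6 5.4069421458104916e-01 4.4944237760817951e-01 3.5704159694413919e-04
6 5.7422041225764575e-01 4.8399389588415020e-01 3.5812517984961181e-04
6 1.8654070272251880e-01 3.2591448510707957e-02 2.5434913299133481e-04
6 2.3211864536894319e-01 6.8356795052973429e-02 2.7867110513307762e-04
6 2.7731591425238822e-01 1.0622848644519890e-01 2.9855523610836787e-04
6 3.2192001922372537e-01 1.4544044093230471e-01 3.1458679291540391e-04
6 3.6570325939440290e-01 1.8540182825825099e-01 3.2732906620676089e-04
6 4.0843767783636220e-01 2.2562974120147500e-01 3.3727055119435012e-04
6 4.4990049457514270e-01 2.6571044250008963e-01 3.4482744378515101e-04
6 4.8987581413263348e-01 3.0527554876315571e-01 3.5035927830485828e-04
6 5.2815474422663089e-01 3.4398639206454229e-01 3.5418547926631622e-04
6 5.6453469898139919e-01 3.8152294561219141e-01 3.5659955179094278e-04
6 5.9881812521598476e-01 4.1757524209667340e-01 3.5788020783028980e-04
6 2.8504254244716032e-01 3.5621495098625361e-02 2.9586445928609821e-04
6 3.3246194330278761e-01 7.3303188868710956e-02 3.1195481291168353e-04
6 3.7858483330762821e-01 1.1232262960084720e-01 3.2507452250059841e-04
6 4.2328910285621152e-01 1.5210841933377081e-01 3.3551534159352082e-04
6 4.6642870508297218e-01 1.9218444592236100e-01 3.4358475685493281e-04
6 5.0784584937357258e-01 2.3213609896783030e-01 3.4957868316224880e-04
6 5.4737798162041795e-01 2.7158864863605198e-01 3.5377678055346212e-04
6 5.8486171338113757e-01 3.1019247075713552e-01 3.5644598154214280e-04
6 6.2013482815848875e-01 3.4761210528909731e-01 3.5784640612254682e-04
6 3.8521911853878710e-01 3.7632248800351077e-02 3.2397487628362123e-04
6 4.3250250610734231e-01 7.6595819356371345e-02 3.3454917841742868e-04
6 4.7784862297344899e-01 1.1633813060839000e-01 3.4291261773017822e-04
6 5.2116636930089999e-01 1.5638905987528989e-01 3.4924203430974210e-04
6 5.6234695048537031e-01 1.9633208101492000e-01 3.5373990502352568e-04
6 6.0127181886592462e-01 2.3578474072587380e-01 3.5662091526591719e-04
6 6.3781792063901166e-01 2.7438461212440601e-01 3.5810843219197822e-04
6 4.8369364602145343e-01 3.8959026107390243e-02 3.4265221175915121e-04
6 5.2937925626837967e-01 7.8712468193126398e-02 3.4918487701213788e-04
6 5.7262812531000329e-01 1.1879638082029810e-01 3.5393182352314761e-04
6 6.1336587761690675e-01 1.5879147080617870e-01 3.5702314384586939e-04
6 6.5150854918653067e-01 1.9830585752276461e-01 3.5862073350517140e-04
6 5.7786927160649759e-01 3.9772096897915422e-02 3.5411962051640249e-04
6 6.2079042880861923e-01 7.9901575929811522e-02 3.5742969115739530e-04
6 6.6086881710468015e-01 1.1996713087543090e-01 3.5919932798189630e-04
6 6.6562630894891295e-01 4.0159559578059688e-02 3.5958550346619971e-04
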