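# Lebedev-Laikov quadrature orbit parameters, rule with 2702 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 2.9986751498881611e-05
3 0.0000000000000000e+00 0.0000000000000000e+00 4.0778605294953548e-04
4 2.0655625388187032e-02 0.0000000000000000e+00 1.1853491925206671e-04
4 5.2509181730223793e-02 0.0000000000000000e+00 1.9134086434257510e-04
4 8.9934800820383756e-02 0.0000000000000000e+00 2.4528865772098968e-04
4 1.3060239244360189e-01 0.0000000000000000e+00 2.8624081832887021e-04
4 1.7320603885314181e-01 0.0000000000000000e+00 3.1780322582573568e-04
4 2.1687270848202489e-01 0.0000000000000000e+00 3.4229456676336902e-04
4 2.6095283091735860e-01 0.0000000000000000e+00 3.6127905202359219e-04
4 3.0492529279389519e-01 0.0000000000000000e+00 3.7586382298185209e-04
4 3.4834841380844039e-01 0.0000000000000000e+00 3.8687117988599532e-04
4 3.9083215491064061e-01 0.0000000000000000e+00 3.9494299331899380e-04
4 4.3202100718948139e-01 0.0000000000000000e+00 4.0060681075411561e-04
4 4.7158247958900529e-01 0.0000000000000000e+00 4.0431921496727232e-04
4 5.0919847940784535e-01 0.0000000000000000e+00 4.0649474958080783e-04
4 5.4455801456508035e-01 0.0000000000000000e+00 4.0752456198131520e-04
4 6.0725757968417682e-01 0.0000000000000000e+00 4.0764235408935657e-04
4 6.3394845057558025e-01 0.0000000000000000e+00 4.0742808622515548e-04
4 6.5707182574869583e-01 0.0000000000000000e+00 4.0741637560122440e-04
4 6.7625573300907094e-01 0.0000000000000000e+00 4.0776477950712461e-04
4 6.9111616969237899e-01 0.0000000000000000e+00 4.0845175527825302e-04
4 7.0128419116599605e-01 0.0000000000000000e+00 4.0924684592240519e-04
4 7.0645592724100204e-01 0.0000000000000000e+00 4.0978726872409061e-04
5 6.1235549898947653e-02 0.0000000000000000e+00 1.7389868117450281e-04
5 1.5330703483123931e-01 0.0000000000000000e+00 2.6596160452801911e-04
5 2.5639026052442060e-01 0.0000000000000000e+00 3.2405960081715332e-04
5 3.6293469916633608e-01 0.0000000000000000e+00 3.6211959644329432e-04
5 4.6839499689875380e-01 0.0000000000000000e+00 3.8688383307605392e-04
5 5.6944792406579525e-01 0.0000000000000000e+00 4.0189115326931112e-04
5 6.6344654309939555e-01 0.0000000000000000e+00 4.0899294329832520e-04
6 1.0339585735523051e-01 3.0345440090635840e-02 2.2799075277064090e-04
6 1.4735214124143950e-01 6.6188030442471346e-02 2.7152054905788968e-04
6 1.9245521587059669e-01 1.0544311289877149e-01 3.0579178967039762e-04
6 2.3810943628903281e-01 1.4682635512388581e-01 3.3269130524525548e-04
6 2.8381217079367599e-01 1.8944861081878861e-01 3.5373347118900368e-04
6 3.2913231333734150e-01 2.3263742387615791e-01 3.7005675007831289e-04
6 3.7368969787414602e-01 2.7584858084857677e-01 3.8252453725891219e-04
6 4.1714060407600129e-01 3.1861793319969212e-01 3.9181251715182962e-04
6 4.5916779852569151e-01 3.6053297963037939e-01 3.9847204199375789e-04
6 4.9947338317184181e-01 4.0121472535865088e-01 4.0297460033382107e-04
6 5.3777318304450961e-01 4.4030500255706922e-01 4.0574286321566269e-04
6 5.7379178300013312e-01 4.7745659042774830e-01 4.0717192741148572e-04
6 2.0273235862713890e-01 3.5441225049761473e-02 2.9902369506641191e-04
6 2.5169423751872733e-01 7.4183043886463282e-02 3.2629517342128779e-04
6 3.0002279952571809e-01 1.1505027457271860e-01 3.4826346082424131e-04
6 3.4748066910463421e-01 1.5719633712093639e-01 3.6565966817008919e-04
6 3.9381031803592093e-01 1.9996318772471000e-01 3.7917404677942178e-04
6 4.3875195904557029e-01 2.4280734578465349e-01 3.8940344501569050e-04
6 4.8205039600777871e-01 2.8525751329061549e-01 3.9686002455083708e-04
6 5.2345737784751012e-01 3.2688842086746389e-01 4.0199313514200502e-04
6 5.6273186472352821e-01 3.6730333216759392e-01 4.0521088012785989e-04
6 5.9963906071569539e-01 4.0612115518302899e-01 4.0689786139409340e-04
6 3.0847807537919469e-01 3.8601255231000588e-02 3.4542753513197040e-04
6 3.5899882759202228e-01 7.9289389871048666e-02 3.6299635370079200e-04
6 4.0786284158819730e-01 1.2126146430300870e-01 3.7701872338898729e-04
6 4.5492872588897348e-01 1.6387708273826929e-01 3.8786086136943782e-04
6 5.0002785129572791e-01 2.0659657982601759e-01 3.9590652702212740e-04
6 5.4297850449281992e-01 2.4894363788522350e-01 4.0152869754635700e-04
6 5.8359398504917115e-01 2.9048113689468907e-01 4.0508667856147169e-04
6 6.2168703534448555e-01 3.3079419576666091e-01 4.0693201850519129e-04
6 4.1511046627090908e-01 4.0648291460525537e-02 3.7601209640627630e-04
6 4.6498042750092178e-01 8.2584245472947557e-02 3.8709695644180642e-04
6 5.1246957570096618e-01 1.2518419620272889e-01 3.9552877905340552e-04
6 5.5747111006062244e-01 1.6791075059763311e-01 4.0153619113026680e-04
6 5.9985973332872267e-01 2.1028050573587151e-01 4.0538369867195481e-04
6 6.3950071485166005e-01 2.5184180877741069e-01 4.0735786732991168e-04
6 5.1884562247462518e-01 4.1943216760775177e-02 3.9546283792314061e-04
6 5.6641907079427778e-01 8.4576615519214984e-02 4.0176455088475300e-04
6 6.1104643532831526e-01 1.2736529325193960e-01 4.0590303486512928e-04
6 6.5264303020515635e-01 1.6981732390763540e-01 4.0805658094848800e-04
6 6.1675518803775475e-01 4.2663988515488638e-02 4.0630187536646510e-04
6 6.6071954183553827e-01 8.5519258142383495e-02 4.0871912927996709e-04
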