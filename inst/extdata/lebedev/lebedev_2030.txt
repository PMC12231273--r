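# Lebedev-Laikov quadrature orbit parameters, rule with 2030 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 4.6560318991974309e-05
3 0.0000000000000000e+00 0.0000000000000000e+00 5.4215491952955069e-04
4 2.5408353368143479e-02 0.0000000000000000e+00 1.7785221333465530e-04
4 6.3993228005049155e-02 0.0000000000000000e+00 2.8113254056827961e-04
4 1.0882694698041250e-01 0.0000000000000000e+00 3.5488963126314592e-04
4 1.5706707988182869e-01 0.0000000000000000e+00 4.0903108971733639e-04
4 2.0711639322825140e-01 0.0000000000000000e+00 4.4932861341699648e-04
4 2.5789140444508440e-01 0.0000000000000000e+00 4.7937284479627232e-04
4 3.0856875581696230e-01 0.0000000000000000e+00 5.0154153191642647e-04
4 3.5847197062670239e-01 0.0000000000000000e+00 5.1751273726779372e-04
4 4.0701355944287088e-01 0.0000000000000000e+00 5.2855222620810190e-04
4 4.5366186262226382e-01 0.0000000000000000e+00 5.3568327037139618e-04
4 4.9791956864635772e-01 0.0000000000000000e+00 5.3979147361751703e-04
4 5.3930751111269992e-01 0.0000000000000000e+00 5.4168994415999296e-04
4 6.1156176768439163e-01 0.0000000000000000e+00 5.4193084768899380e-04
4 6.4143084351601587e-01 0.0000000000000000e+00 5.4169369020305963e-04
4 6.6640994127216069e-01 0.0000000000000000e+00 5.4195443387031639e-04
4 6.8591617712149133e-01 0.0000000000000000e+00 5.4289836566309745e-04
4 6.9936255935038905e-01 0.0000000000000000e+00 5.4422865000981931e-04
4 7.0623933877193801e-01 0.0000000000000000e+00 5.4522503450573007e-04
5 7.4790281683497634e-02 0.0000000000000000e+00 2.5680024977285302e-04
5 1.8489511539693659e-01 0.0000000000000000e+00 3.8272117002921449e-04
5 3.0595290665813052e-01 0.0000000000000000e+00 4.5794915619178241e-04
5 4.2855561010213622e-01 0.0000000000000000e+00 5.0420039690835742e-04
5 5.4687586534965260e-01 0.0000000000000000e+00 5.3127088899760245e-04
5 6.5658219783434391e-01 0.0000000000000000e+00 5.4384017907471174e-04
6 1.2539015723671171e-01 3.6819172264396412e-02 3.3160418731973442e-04
6 1.7757215103839410e-01 7.9824876072133011e-02 3.8991135671537713e-04
6 2.3056933582161140e-01 1.2646409665923350e-01 4.3433433272013089e-04
6 2.8365028459920633e-01 1.7515856834189569e-01 4.6794152623189192e-04
6 3.3617947462325898e-01 2.2479959076326700e-01 4.9308479816310307e-04
6 3.8759791722648240e-01 2.7452992574222462e-01 5.1150318675400913e-04
6 4.3740193169990738e-01 3.2363734824411178e-01 5.2452171484573666e-04
6 4.8512758433400222e-01 3.7149678594367408e-01 5.3320414998953209e-04
6 5.3033918038068684e-01 4.1753536463217450e-01 5.3845831260215425e-04
6 5.7261973805962874e-01 4.6120844063554611e-01 5.4110672107988522e-04
6 2.4315207325648630e-01 4.2580401330439520e-02 4.2597973914687142e-04
6 3.0020968008958693e-01 8.8694243067227216e-02 4.6049313684600211e-04
6 3.5585544574574318e-01 1.3688117065106550e-01 4.8718148782552021e-04
6 4.0977825370488868e-01 1.8607399850150330e-01 5.0722429100748853e-04
6 4.6163376660674582e-01 2.3542350773958531e-01 5.2170698452353500e-04
6 5.1107070084178741e-01 2.8420749213470109e-01 5.3157859662803105e-04
6 5.5774152861637949e-01 3.3177844149841018e-01 5.3768337087589050e-04
6 6.0130604313669500e-01 3.7752990020407001e-01 5.4080320920695207e-04
6 3.6615967672617811e-01 4.5993678871645918e-02 4.8427449179048662e-04
6 4.2376331535065809e-01 9.4048937736544214e-02 5.0489260761881296e-04
6 4.7863284546584522e-01 1.4313771090919711e-01 5.2026079804783727e-04
6 5.3057020767897745e-01 1.9241863888435701e-01 5.3099323883257427e-04
6 5.7934362242317883e-01 2.4115909447751899e-01 5.3774197708952084e-04
6 6.2470690170947474e-01 2.8868714915836052e-01 5.4116963316777167e-04
6 4.8743155525352039e-01 4.8049787749532058e-02 5.1979962932824201e-04
6 5.4273373220590526e-01 9.7168571993666644e-02 5.3111208366229447e-04
6 5.9434937472466998e-01 1.4652058397950549e-01 5.3843093199569514e-04
6 6.4213140335649432e-01 1.9535794498035741e-01 5.4218595040518862e-04
6 6.0206283747139799e-01 4.9163750157381080e-02 5.3909483550463135e-04
6 6.5292225298568807e-01 9.8616215401270052e-02 5.4333127050278454e-04
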