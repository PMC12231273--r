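# Lebedev-Laikov quadrature orbit parameters, rule with 4334 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 1.4490630225378830e-05
3 0.0000000000000000e+00 0.0000000000000000e+00 2.5463773298284239e-04
4 1.4628961518310130e-02 0.0000000000000000e+00 6.0184329610874963e-05
4 3.7698408124931387e-02 0.0000000000000000e+00 1.0022865832636730e-04
4 6.5247019040968912e-02 0.0000000000000000e+00 1.3152229310280930e-04
4 9.5605434161346481e-02 0.0000000000000000e+00 1.5642137468767239e-04
4 1.2783358989291979e-01 0.0000000000000000e+00 1.7651188415077361e-04
4 1.6130961044660311e-01 0.0000000000000000e+00 1.9287370993110800e-04
4 1.9558062257453709e-01 0.0000000000000000e+00 2.0626585342632699e-04
4 2.3029352184980281e-01 0.0000000000000000e+00 2.1723954459537871e-04
4 2.6515843441130271e-01 0.0000000000000000e+00 2.2620761888760471e-04
4 2.9992768251832091e-01 0.0000000000000000e+00 2.3348856994623971e-04
4 3.3438286697187980e-01 0.0000000000000000e+00 2.3933552731792031e-04
4 3.6832650137505180e-01 0.0000000000000000e+00 2.4395592004688630e-04
4 4.0157632065181081e-01 0.0000000000000000e+00 2.4752518660600020e-04
4 4.3396120263997701e-01 0.0000000000000000e+00 2.5019655581587732e-04
4 4.6531806511145818e-01 0.0000000000000000e+00 2.5210814079259250e-04
4 4.9548933310808030e-01 0.0000000000000000e+00 2.5338810023880809e-04
4 5.2432070689249299e-01 0.0000000000000000e+00 2.5415829008482610e-04
4 5.5165904790417042e-01 0.0000000000000000e+00 2.5453657375258600e-04
4 6.0123719278041765e-01 0.0000000000000000e+00 2.5457269930667989e-04
4 6.2315744664498185e-01 0.0000000000000000e+00 2.5444561974655551e-04
4 6.4294165141812709e-01 0.0000000000000000e+00 2.5434815968810638e-04
4 6.6041242729435945e-01 0.0000000000000000e+00 2.5435064514291942e-04
4 6.7538514704082497e-01 0.0000000000000000e+00 2.5449056754937632e-04
4 6.8767179706261605e-01 0.0000000000000000e+00 2.5476114073444292e-04
4 6.9708950613192344e-01 0.0000000000000000e+00 2.5510603754488691e-04
4 7.0347469125533102e-01 0.0000000000000000e+00 2.5542919338160391e-04
4 7.0670172175422952e-01 0.0000000000000000e+00 2.5562557106863432e-04
5 4.3822235011311231e-02 0.0000000000000000e+00 9.0413396951181957e-05
5 1.1174740774000060e-01 0.0000000000000000e+00 1.4384263300790221e-04
5 1.8971532529114399e-01 0.0000000000000000e+00 1.8025230898205180e-04
5 2.7240230099103308e-01 0.0000000000000000e+00 2.0600522905654960e-04
5 3.5671633087099019e-01 0.0000000000000000e+00 2.2450022489674661e-04
5 4.4047844830280869e-01 0.0000000000000000e+00 2.3770598477311500e-04
5 5.2198331541614107e-01 0.0000000000000000e+00 2.4681189558825248e-04
5 5.9981798689775534e-01 0.0000000000000000e+00 2.5254108729665282e-04
5 6.7278031545482220e-01 0.0000000000000000e+00 2.5531014099333969e-04
6 7.4765639431660855e-02 2.1931685094611849e-02 1.2128797336686320e-04
6 1.0753414820014159e-01 4.8264192815338870e-02 1.4728728812709311e-04
6 1.4163448852032590e-01 7.7511918835757421e-02 1.6868466010108279e-04
6 1.7663253153885861e-01 1.0875581392476801e-01 1.8626984146602081e-04
6 2.1217441744815141e-01 1.4136613742530960e-01 2.0074309569918610e-04
6 2.4796694434081451e-01 1.7487682142588801e-01 2.1265681253947961e-04
6 2.8376004522941128e-01 2.0892164066120730e-01 2.2243946033721130e-04
6 3.1933449331939839e-01 2.4319876855459721e-01 2.3042645226731349e-04
6 3.5449354424387453e-01 2.7744970543777697e-01 2.3688542884240871e-04
6 3.8905719322881538e-01 3.1144603561569151e-01 2.4203520894617721e-04
6 4.2285812142590901e-01 3.4498068519130121e-01 2.4605971130812950e-04
6 4.5573872113040520e-01 3.7786186412482559e-01 2.4911819122576872e-04
6 4.8754879505416432e-01 4.0990863916989778e-01 2.5135281942058568e-04
6 5.1814365299629972e-01 4.4094749258539728e-01 2.5289430966932201e-04
6 5.4738240956006612e-01 4.7080945177112909e-01 2.5386603684881360e-04
6 5.7512633989761741e-01 4.9932751403546372e-01 2.5438686482990219e-04
6 1.4895157468400280e-01 2.5993819932670172e-02 1.6425955378251831e-04
6 1.8636564443517670e-01 5.4792865324621902e-02 1.8182466598493080e-04
6 2.2386028803563479e-01 8.5567632514252534e-02 1.9665656494924201e-04
6 2.6127233757281598e-01 1.1772578022670110e-01 2.0906779056579911e-04
6 2.9843329902061899e-01 1.5081684561927000e-01 2.1938204095105039e-04
6 3.3517865846633332e-01 1.8448018921777271e-01 2.2788708276619279e-04
6 3.7135055222091201e-01 2.1841452360875979e-01 2.3482831922820899e-04
6 4.0679810989546628e-01 2.5235906414862291e-01 2.4041397555814770e-04
6 4.4137699936875341e-01 2.8608129769013729e-01 2.4482274077607341e-04
6 4.7494871825163942e-01 3.1936867578089961e-01 2.4821104555925729e-04
6 5.0737981050754255e-01 3.5202269495476018e-01 2.5071923977741033e-04
6 5.3854104488786536e-01 3.8385443956678900e-01 2.5247659685348798e-04
6 5.6830653536705300e-01 4.1468100376409628e-01 2.5360523885394249e-04
6 5.9655276206635099e-01 4.4432240946811208e-01 2.5422305880330682e-04
6 2.2992277008561571e-01 2.8657576640575839e-02 1.9448170130478959e-04
6 2.6957529985532669e-01 5.9234216844859931e-02 2.0678623627466350e-04
6 3.0861787166113891e-01 9.1178177760577156e-02 2.1724407346491141e-04
6 3.4696498716590768e-01 1.2405938140826051e-01 2.2601259917234229e-04
6 3.8451535663196551e-01 1.5752720582591750e-01 2.3326550086895229e-04
6 4.2116000334032150e-01 1.9128451635254129e-01 2.3916996815324579e-04
6 4.5678678343298817e-01 2.2507101778581709e-01 2.4388015282739281e-04
6 4.9128293192320610e-01 2.5865213034409101e-01 2.4753705042606652e-04
6 5.2453647933038117e-01 2.9181122428654072e-01 2.5027072356405739e-04
6 5.5643697889157562e-01 3.2434392390678901e-01 2.5220317010542410e-04
6 5.8687576977752876e-01 3.5605367878353511e-01 2.5345112699787838e-04
6 6.1574588535196173e-01 3.8674808212425810e-01 2.5412849149551508e-04
6 3.1384611106721128e-01 3.0513746375072780e-02 2.1615092506883940e-04
6 3.5424958720505689e-01 6.2371112337307549e-02 2.2487785134378519e-04
6 3.9357515531201809e-01 9.5162239524019074e-02 2.3223888034046170e-04
6 4.3176346681111472e-01 1.2854673415085169e-01 2.3832654710013551e-04
6 4.6874138422508210e-01 1.6223189316560330e-01 2.4324766750195251e-04
6 5.0442742370602833e-01 1.9595811538364530e-01 2.4711222237506738e-04
6 5.3873540779257267e-01 2.2948880811838371e-01 2.5002917524868701e-04
6 5.7157688983561050e-01 2.6260311527139452e-01 2.5210559427646818e-04
6 6.0286272001361108e-01 2.9509040752867127e-01 2.5344727855755030e-04
6 6.3250398126534635e-01 3.2674584511132859e-01 2.5415997130801211e-04
6 3.9819867084234067e-01 3.1832914587498207e-02 2.3173809758629359e-04
6 4.3827911821332999e-01 6.4595481938809082e-02 2.3785507337197750e-04
6 4.7692330572181663e-01 9.7957570370879515e-02 2.4288844567391181e-04
6 5.1408239111942378e-01 1.3163072351266550e-01 2.4690026557572920e-04
6 5.4969778338629827e-01 1.6535564863587041e-01 2.4996575742658510e-04
6 5.8370473065127271e-01 1.9889317241265100e-01 2.5216761684860819e-04
6 6.1603495669268793e-01 2.3201745814389499e-01 2.5359356626453340e-04
6 6.4661853532094404e-01 2.6451065621686620e-01 2.5433567433632138e-04
6 4.8108351587954040e-01 3.2759178077439922e-02 2.4273532852015349e-04
6 5.1999250413243414e-01 6.6125461839671815e-02 2.4682580397443861e-04
6 5.5717176922074940e-01 9.9814983314741423e-02 2.5000609564403099e-04
6 5.9257892508363785e-01 1.3356870014103739e-01 2.5232383654209790e-04
6 6.2616585238596700e-01 1.6714444028964631e-01 2.5383992602528462e-04
6 6.5788111266693305e-01 2.0031063821560760e-01 2.5462559272680690e-04
6 5.6096246129980998e-01 3.3375009402313353e-02 2.5005833600484488e-04
6 5.9799596599846705e-01 6.7087503359018030e-02 2.5247776382602031e-04
6 6.3305237110540025e-01 1.0087921264248501e-01 2.5409511938606562e-04
6 6.6609609981039719e-01 1.3450503431717939e-01 2.5495240850274722e-04
6 6.3653843645858188e-01 3.3727994607370519e-02 2.5425695070091579e-04
6 6.7109943028992747e-01 6.7552493096780283e-02 2.5521141275803758e-04
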