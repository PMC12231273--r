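# Lebedev-Laikov quadrature orbit parameters, rule with 3890 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 1.8073952521969199e-05
2 0.0000000000000000e+00 0.0000000000000000e+00 2.8480087822388271e-04
3 0.0000000000000000e+00 0.0000000000000000e+00 2.8360658375305809e-04
4 1.5878764198583521e-02 0.0000000000000000e+00 7.0131492666738158e-05
4 4.0691935937512060e-02 0.0000000000000000e+00 1.1627980219567660e-04
4 7.0258881152579972e-02 0.0000000000000000e+00 1.5187285839721049e-04
4 1.0274954500287040e-01 0.0000000000000000e+00 1.7987961082169341e-04
4 1.3714577308934259e-01 0.0000000000000000e+00 2.0225933859727849e-04
4 1.7277585326719530e-01 0.0000000000000000e+00 2.2030931055754639e-04
4 2.0914920389290370e-01 0.0000000000000000e+00 2.3492942342998551e-04
4 2.4588132817519151e-01 0.0000000000000000e+00 2.4676820587470028e-04
4 2.8265458594500659e-01 0.0000000000000000e+00 2.5630926835722238e-04
4 3.1919572917996220e-01 0.0000000000000000e+00 2.6392538967633182e-04
4 3.5526214692995778e-01 0.0000000000000000e+00 2.6991374792651081e-04
4 3.9063295034062301e-01 0.0000000000000000e+00 2.7451964201667391e-04
4 4.2510286140930309e-01 0.0000000000000000e+00 2.7795291973975933e-04
4 4.5847775201118701e-01 0.0000000000000000e+00 2.8039960866842650e-04
4 4.9057113587101930e-01 0.0000000000000000e+00 2.8203023567158420e-04
4 5.2120116698473851e-01 0.0000000000000000e+00 2.8300567474910681e-04
4 5.5018784887379946e-01 0.0000000000000000e+00 2.8348089507768392e-04
4 6.0250378774793423e-01 0.0000000000000000e+00 2.8352823390789291e-04
4 6.2545726895490161e-01 0.0000000000000000e+00 2.8338192670657999e-04
4 6.4601071795282483e-01 0.0000000000000000e+00 2.8328583369067838e-04
4 6.6395411381542513e-01 0.0000000000000000e+00 2.8332682354512438e-04
4 6.7906885156674945e-01 0.0000000000000000e+00 2.8354326770292529e-04
4 6.9113385803715122e-01 0.0000000000000000e+00 2.8390917227430490e-04
4 6.9993859561264904e-01 0.0000000000000000e+00 2.8433081788758411e-04
4 7.0530377486568963e-01 0.0000000000000000e+00 2.8467035505338458e-04
5 4.7322243871801152e-02 0.0000000000000000e+00 1.0511934069719000e-04
5 1.2021005293268031e-01 0.0000000000000000e+00 1.6578718387969739e-04
5 2.0343048206648551e-01 0.0000000000000000e+00 2.0646481137142321e-04
5 2.9122856435730021e-01 0.0000000000000000e+00 2.3479427458197410e-04
5 3.8023617927267678e-01 0.0000000000000000e+00 2.5477753265977260e-04
5 4.6805985110561460e-01 0.0000000000000000e+00 2.6868766848470253e-04
5 5.5281510521555988e-01 0.0000000000000000e+00 2.7786657555158668e-04
5 6.3293863078030410e-01 0.0000000000000000e+00 2.8309966167829292e-04
6 8.0565166513690695e-02 2.3634546840031238e-02 1.4030633401683720e-04
6 1.1564760771393889e-01 5.1912916325459357e-02 1.6965041259394770e-04
6 1.5204733827604211e-01 8.3227157369945196e-02 1.9357872427453899e-04
6 1.8929866997459310e-01 1.1658556679937120e-01 2.1306145105219680e-04
6 2.2701944467777921e-01 1.5130771674095039e-01 2.2893812659310480e-04
6 2.6489081850932727e-01 1.8688820258078589e-01 2.4186302928161859e-04
6 3.0263892595741360e-01 2.2292776297762240e-01 2.5234004956311927e-04
6 3.4002202961513839e-01 2.5909518407462351e-01 2.6076239734496048e-04
6 3.7682179533355098e-01 2.9510472917508468e-01 2.6744410326892090e-04
6 4.1283729009218839e-01 3.3070197141699298e-01 2.7264323603433562e-04
6 4.4788071318156297e-01 3.6565441010876337e-01 2.7657876859245453e-04
6 4.8177420340892568e-01 3.9974489519396950e-01 2.7944286906422241e-04
6 5.1434728146533437e-01 4.3276671108120240e-01 2.8140990020628949e-04
6 5.4543462139056498e-01 4.6451961235322931e-01 2.8264295315789939e-04
6 5.7487393131702524e-01 4.9480635557033448e-01 2.8329835425508840e-04
6 1.5995987382863419e-01 2.7923575900489848e-02 1.8866955652849761e-04
6 1.9980974125009510e-01 5.8771410381390651e-02 2.0818678827482339e-04
6 2.3962289525662020e-01 9.1645739146913777e-02 2.2451486806007961e-04
6 2.7922283410977461e-01 1.2590496419626870e-01 2.3803704915118719e-04
6 3.1842511075467411e-01 1.6105948234008630e-01 2.4913980418524552e-04
6 3.5704811644262441e-01 1.9671516534608979e-01 2.5816324058812299e-04
6 3.9491647104921440e-01 2.3254046061751679e-01 2.6539655062274167e-04
6 4.3186172939705031e-01 2.6824611411514387e-01 2.7108572167470872e-04
6 4.6772210099316780e-01 3.0357201160119729e-01 2.7544340939036590e-04
6 5.0234179392709555e-01 3.3827818591974390e-01 2.7865799325193803e-04
6 5.3557018366361275e-01 3.7213830656259422e-01 2.8090110806794740e-04
6 5.6726084513287711e-01 4.0493463604660551e-01 2.8233361845609868e-04
6 5.9727042025401622e-01 4.3645380986338023e-01 2.8311011758063088e-04
6 2.4616870223335960e-01 3.0704231668333679e-02 2.2216799703545461e-04
6 2.8817745662868310e-01 6.3380346692818848e-02 2.3561857342707031e-04
6 3.2939636041169779e-01 9.7428624870679409e-02 2.4692283448055899e-04
6 3.6973038222413768e-01 1.3237995322822901e-01 2.5627263486420460e-04
6 4.0906630231351271e-01 1.6784970181293360e-01 2.6387567267530278e-04
6 4.4728193554117118e-01 2.0350951053261140e-01 2.6993111573908618e-04
6 4.8425133772314372e-01 2.3906925666720910e-01 2.7462332684038369e-04
6 5.1984776299629276e-01 2.7426498180761488e-01 2.7812256744547711e-04
6 5.5394530118831453e-01 3.0885038065800940e-01 2.8058812540456842e-04
6 5.8641967624012514e-01 3.4259042459066141e-01 2.8217198770049128e-04
6 6.1714844666683899e-01 3.7525622947894682e-01 2.8302225023331238e-04
6 3.3503378305657272e-01 3.2615899346347468e-02 2.4579959567448700e-04
6 3.7757732247582843e-01 6.6584389280815726e-02 2.5514744075037061e-04
6 4.1881552298489733e-01 1.0145657971579540e-01 2.6290653351953111e-04
6 4.5868058920093441e-01 1.3685733208438219e-01 2.6919004499250748e-04
6 4.9708957142242349e-01 1.7246148519516080e-01 2.7412754857542758e-04
6 5.3395051339607469e-01 2.0797793814164120e-01 2.7785309701225950e-04
6 5.6916657925314396e-01 2.4313857883222881e-01 2.8050105676467407e-04
6 6.0263876826803775e-01 2.7769018830498532e-01 2.8220558340310398e-04
6 6.3426761501633067e-01 3.1138813563866319e-01 2.8310169012434728e-04
6 4.2379511195370673e-01 3.3948778486643509e-02 2.6244749011318031e-04
6 4.6569186832349291e-01 6.8802195562914475e-02 2.6880341630393769e-04
6 5.0588570691859802e-01 1.0419468597216350e-01 2.7389327512876362e-04
6 5.4432046667139955e-01 1.3980397387363930e-01 2.7779447912425231e-04
6 5.8092988137597423e-01 1.7533733811961549e-01 2.8060116616609868e-04
6 6.1564160394471279e-01 2.1052157935140101e-01 2.8241814565974598e-04
6 6.4838013510666037e-01 2.4509533121570509e-01 2.8335852165778277e-04
6 5.1036165772516884e-01 3.4855606438007190e-02 2.7381652369628780e-04
6 5.5067387925806810e-01 7.0263086315120335e-02 2.7783652082031803e-04
6 5.8895730409952918e-01 1.0590350612964031e-01 2.8078529404189660e-04
6 6.2516415895169297e-01 1.4148239252360259e-01 2.8272459496747051e-04
6 6.5924149215701777e-01 1.7672079082145301e-01 2.8373423448298279e-04
6 5.9303140175333835e-01 3.5421893395616723e-02 2.8092339076109810e-04
6 6.3098122533901746e-01 7.1095740403695484e-02 2.8299308097426938e-04
6 6.6662960113532299e-01 1.0672597922827300e-01 2.8410978741114789e-04
6 6.7037152710499215e-01 3.5694552688208092e-02 2.8434552060087830e-04
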