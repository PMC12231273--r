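# Lebedev-Laikov quadrature orbit parameters, rule with 1730 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 6.3090494374209763e-05
2 0.0000000000000000e+00 0.0000000000000000e+00 6.3982877055717476e-04
3 0.0000000000000000e+00 0.0000000000000000e+00 6.3571850735307195e-04
4 2.8609231261946620e-02 0.0000000000000000e+00 2.2212071621881681e-04
4 7.1425567677115220e-02 0.0000000000000000e+00 3.4757840222868479e-04
4 1.2091995409955590e-01 0.0000000000000000e+00 4.3507424435898040e-04
4 1.7386731065943789e-01 0.0000000000000000e+00 4.9785691365221267e-04
4 2.2846454384677339e-01 0.0000000000000000e+00 5.4350362219980533e-04
4 2.8348076717015119e-01 0.0000000000000000e+00 5.7659133882195421e-04
4 3.3796801454673392e-01 0.0000000000000000e+00 6.0012003592260028e-04
4 3.9113554548195367e-01 0.0000000000000000e+00 6.1621781727175121e-04
4 4.4228603530014032e-01 0.0000000000000000e+00 6.2652181524384845e-04
4 4.9077815687260568e-01 0.0000000000000000e+00 6.3239871609742121e-04
4 5.3600061532114684e-01 0.0000000000000000e+00 6.3507678515405694e-04
4 6.1421059735966033e-01 0.0000000000000000e+00 6.3543627752971066e-04
4 6.4593003879775035e-01 0.0000000000000000e+00 6.3523024627062355e-04
4 6.7180561250892246e-01 0.0000000000000000e+00 6.3581178814179717e-04
4 6.9108885331862535e-01 0.0000000000000000e+00 6.3731015903101165e-04
4 7.0304674168232517e-01 0.0000000000000000e+00 6.3904289613686647e-04
5 8.3549511663546461e-02 0.0000000000000000e+00 3.1869134499465759e-04
5 2.0501430090994860e-01 0.0000000000000000e+00 4.6780285585917110e-04
5 3.3702082907066372e-01 0.0000000000000000e+00 5.5388296975986259e-04
5 4.6890514842339631e-01 0.0000000000000000e+00 6.0444759071904761e-04
5 5.9394004245573340e-01 0.0000000000000000e+00 6.3135751035090122e-04
6 1.3949833118322610e-01 4.0975811620503427e-02 4.0786264318556302e-04
6 1.9679991804850139e-01 8.8519873912933478e-02 4.7599330578127250e-04
6 2.5461837325489672e-01 1.3976801829698191e-01 5.2681511864134396e-04
6 3.1212810747138747e-01 1.9294525422265260e-01 5.6430485605073156e-04
6 3.6859810785024921e-01 2.4678983370615620e-01 5.9145010766130726e-04
6 4.2337603215478559e-01 3.0031041247854090e-01 6.1045612578741954e-04
6 4.7586712360592459e-01 3.5266843281750332e-01 6.2302528607078060e-04
6 5.2551785797964634e-01 4.0311348611457132e-01 6.3056187617607957e-04
6 5.7180256337345892e-01 4.5094264483423507e-01 6.3430927675978892e-04
6 2.6869277727234148e-01 4.7113225024232479e-02 5.1762689457378265e-04
6 3.3060068199048093e-01 9.7844873039426947e-02 5.5648403133136924e-04
6 3.9049068505949830e-01 1.5053958100252729e-01 5.8564266710389799e-04
6 4.4799579519043897e-01 2.0397281562960501e-01 6.0663869257770911e-04
6 5.0270768489197803e-01 2.5715299411211068e-01 6.2088249622344581e-04
6 5.5420873922602165e-01 3.0921913758156699e-01 6.2963142978229066e-04
6 6.0208508873751865e-01 3.5938075061302760e-01 6.3404237567918592e-04
6 4.0198514091795939e-01 5.0633899343786710e-02 5.8296276771073420e-04
6 4.6356145674498000e-01 1.0324222691606121e-01 6.0486933760811102e-04
6 5.2158609315915749e-01 1.5663220940062539e-01 6.2023623177324613e-04
6 5.7582024990992708e-01 2.0980828274910990e-01 6.2990053284037791e-04
6 6.2598936838767949e-01 2.6188241145533908e-01 6.3477223906093525e-04
6 5.3137951248118909e-01 5.2632450193385562e-02 6.2037789812388340e-04
6 5.8933179559319948e-01 1.0610597309820050e-01 6.3084146712399794e-04
6 6.4262463212158005e-01 1.5941715640342211e-01 6.3627064669594981e-04
6 6.5119043673761134e-01 5.3547895365655400e-02 6.3754141703332328e-04
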