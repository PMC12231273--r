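# Lebedev-Laikov quadrature orbit parameters, rule with 1454 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 7.7771607432612467e-05
3 0.0000000000000000e+00 0.0000000000000000e+00 7.5576464130047011e-04
4 3.2292906634138543e-02 0.0000000000000000e+00 2.8416338060906172e-04
4 8.0367332714622222e-02 0.0000000000000000e+00 4.3744191270535552e-04
4 1.3542899605316530e-01 0.0000000000000000e+00 5.4171747408721723e-04
4 1.9389638611144261e-01 0.0000000000000000e+00 6.1480008913585927e-04
4 2.5373437150112749e-01 0.0000000000000000e+00 6.6643944858007045e-04
4 3.1352514347525701e-01 0.0000000000000000e+00 7.0250393569232196e-04
4 3.7215583393753382e-01 0.0000000000000000e+00 7.2685117892496267e-04
4 4.2868095751956958e-01 0.0000000000000000e+00 7.4226375342086287e-04
4 4.8225101282829941e-01 0.0000000000000000e+00 7.5095450358412142e-04
4 5.3206793335662628e-01 0.0000000000000000e+00 7.5485350577184009e-04
4 6.1729981953942736e-01 0.0000000000000000e+00 7.5540889697740007e-04
4 6.5106798491274809e-01 0.0000000000000000e+00 7.5531471744428084e-04
4 6.7773152516873603e-01 0.0000000000000000e+00 7.5647676532922974e-04
4 6.9631094106487412e-01 0.0000000000000000e+00 7.5879918085187297e-04
4 7.0589350098317494e-01 0.0000000000000000e+00 7.6082618320330272e-04
5 9.9555461940918566e-01 0.0000000000000000e+00 4.0216804478749159e-04
5 9.7341159017942092e-01 0.0000000000000000e+00 5.8048717939459637e-04
5 9.2756937323886257e-01 0.0000000000000000e+00 6.7921519559451589e-04
5 8.5680224227951030e-01 0.0000000000000000e+00 7.3367412112862939e-04
5 7.6234955537193716e-01 0.0000000000000000e+00 7.5818663009896085e-04
6 5.7075229088922230e-01 4.3870280398895012e-01 7.5382578598007428e-04
6 5.1964633884030831e-01 3.8589084147626168e-01 7.4835172470531233e-04
6 4.6463375312153510e-01 3.3019373723438539e-01 7.3717636611120589e-04
6 4.0639016975576908e-01 2.7254235735637772e-01 7.1834488957569337e-04
6 3.4563294666430872e-01 2.1395102374952499e-01 6.8958155298221913e-04
6 2.8313951210503319e-01 1.5559223097866470e-01 6.4801058017928859e-04
6 2.1976820229253299e-01 9.8928789796860969e-02 5.8975588965946358e-04
6 1.5646960986503550e-01 4.5986429106755100e-02 5.0957088492473461e-04
6 6.0273566737212947e-01 3.3766251401734260e-01 7.5369064289097548e-04
6 5.4960323202550965e-01 2.8223013097279881e-01 7.4725059655751181e-04
6 4.9217077552345673e-01 2.2486323425925400e-01 7.3430171322796977e-04
6 4.3094229985984828e-01 1.6662247234564789e-01 7.1308715821774451e-04
6 3.6641081823136717e-01 1.0869649018221690e-01 6.8170220321127763e-04
6 2.9901890577584361e-01 5.2519897841200848e-02 6.3809411456041212e-04
6 6.2687240131449984e-01 2.2975236575500230e-01 7.5503813779203102e-04
6 5.7073241448346068e-01 1.7230806070938001e-01 7.4786466401448022e-04
6 5.0963609019603651e-01 1.1402384653905130e-01 7.3359187206012205e-04
6 4.4387299383124562e-01 5.6115220958825367e-02 7.1101205276581181e-04
6 6.4199784710823893e-01 1.1641744231408729e-01 7.5713639786895008e-04
6 5.8172180618026115e-01 5.7975895314452193e-02 7.4899083290792335e-04
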