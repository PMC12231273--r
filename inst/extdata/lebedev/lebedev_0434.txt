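# Lebedev-Laikov quadrature orbit parameters, rule with 434 points
# columns: orbit_type a b weight   (weights per point, sum over rule = 1)
1 0.0000000000000000e+00 0.0000000000000000e+00 5.2658979682244358e-04
2 0.0000000000000000e+00 0.0000000000000000e+00 2.5482199720026069e-03
3 0.0000000000000000e+00 0.0000000000000000e+00 2.5123174189273069e-03
4 6.9093463075091111e-01 0.0000000000000000e+00 2.5304038011863552e-03
4 1.7748360546091579e-01 0.0000000000000000e+00 2.0142790209185281e-03
4 4.9143426377847460e-01 0.0000000000000000e+00 2.5017251684029359e-03
4 6.4566647074242556e-01 0.0000000000000000e+00 2.5132671745975639e-03
4 2.8612890103076383e-01 0.0000000000000000e+00 2.3026947822274162e-03
4 7.5680843671780185e-02 0.0000000000000000e+00 1.4624956215946140e-03
4 3.9272597633680018e-01 0.0000000000000000e+00 2.4453734373129799e-03
5 8.8181328777942880e-01 0.0000000000000000e+00 2.4174423756389810e-03
5 9.7764281111826490e-01 0.0000000000000000e+00 1.9109512821795321e-03
6 2.0548236964030439e-01 8.6894603228724121e-01 2.4169300443247750e-03
6 5.9051570489252714e-01 7.9992785438572855e-01 2.5122368545634952e-03
6 5.5501523610768067e-01 7.7174626269159008e-01 2.4966440545530861e-03
6 9.3718098585537224e-01 3.3443631453434552e-01 2.2366077604378488e-03
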