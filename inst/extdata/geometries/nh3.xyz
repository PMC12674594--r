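4
optimized with neodh B3LYP/synTZ (synthetic basis), cyclic quadratic refinement; charge 0
N       0.000000000000     0.000000000000     0.000000000000
H       0.941971482432     0.000000000000    -0.371717432850
H      -0.470985741216     0.815771233427    -0.371717432850
H      -0.470985741216    -0.815771233427    -0.371717432850
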