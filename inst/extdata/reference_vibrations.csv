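"reaction","dE_vib_kcal","temperature_K","level"
"nh3_protonation",9.52679530342323,298.15,"B3LYP/synTZ harmonic, finite-difference Hessian (neodh engine)"
"no2_protonation",7.99799399832861,298.15,"B3LYP/synTZ harmonic, finite-difference Hessian (neodh engine)"
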