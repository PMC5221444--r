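# Standard registry of anaerobic reactions (kJ per reaction as written).
# dG0' values from the standard literature compilations for pH 7, 1 mol/L
# solutes, 1 atm gases. Signed coefficients: negative = consumed.
- name: propionate_oxidation
  stoichiometry:
    propionate: -1.0
    H2O: -3.0
    acetate: 1.0
    HCO3-: 1.0
    H+: 1.0
    H2: 3.0
  dg0_prime: 76.1
- name: hydrogenotrophic_methanogenesis
  stoichiometry:
    H2: -4.0
    HCO3-: -1.0
    H+: -1.0
    CH4: 1.0
    H2O: 3.0
  dg0_prime: -135.6
- name: acetoclastic_methanogenesis
  stoichiometry:
    acetate: -1.0
    H2O: -1.0
    CH4: 1.0
    HCO3-: 1.0
  dg0_prime: -31.0
- name: sao
  stoichiometry:
    acetate: -1.0
    H2O: -4.0
    HCO3-: 2.0
    H2: 4.0
    H+: 1.0
  dg0_prime: 104.6
- name: aha
  stoichiometry:
    acetate: 1.0
    H2O: 4.0
    HCO3-: -2.0
    H2: -4.0
    H+: -1.0
  dg0_prime: -104.6
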