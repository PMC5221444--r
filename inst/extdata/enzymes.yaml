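# ARDRA restriction enzymes, standard catalogue recognition sites.
# cut_offset: the enzyme cuts the top strand after this many bases of the
# recognition site (e.g. GCG^C has cut_offset 3). All sites are
# reverse-complement palindromes (asserted at load).
- name: HhaI
  recognition: GCGC
  cut_offset: 3
- name: HinfI
  recognition: GANTC
  cut_offset: 1
- name: HaeIII
  recognition: GGCC
  cut_offset: 2
- name: SmaI
  recognition: CCCGGG
  cut_offset: 3
- name: XhoI
  recognition: CTCGAG
  cut_offset: 1
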