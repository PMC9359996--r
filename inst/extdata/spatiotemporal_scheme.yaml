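# Default spatiotemporal grouping of developmental-brain samples:
# eight temporal groups (p1-p8) defined on age labels and four regional
# groups (r1-r4) defined on region labels. Ages are "<number> pcw|mos|yrs";
# bin boundaries are inclusive. Ages falling between bins are rejected.
temporal:
  - {group: p1, unit: pcw, min: 8,  max: 13}   # first trimester
  - {group: p2, unit: pcw, min: 16, max: 26}   # second trimester
  - {group: p3, unit: pcw, min: 35, max: 37}   # third trimester
  - {group: p4, unit: mos, min: 4,  max: 10}
  - {group: p5, unit: yrs, min: 1,  max: 4}
  - {group: p6, unit: yrs, min: 8,  max: 13}
  - {group: p7, unit: yrs, min: 15, max: 19}
  - {group: p8, unit: yrs, min: 21, max: 40}
regional:
  r1:
    - posterior inferior parietal cortex
    - primary auditory cortex
    - primary visual cortex
    - superior temporal cortex
    - inferior temporal cortex
  r2:
    - primary somatosensory cortex
    - primary motor cortex
    - orbital prefrontal cortex
    - dorsolateral prefrontal cortex
    - medial prefrontal cortex
    - ventrolateral prefrontal cortex
  r3:
    - striatum
    - hippocampus
    - amygdala
  r4:
    - mediodorsal nucleus of the thalamus
    - cerebellar cortex
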