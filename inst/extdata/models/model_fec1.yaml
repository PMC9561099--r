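# First-year faecal Strongyle egg count, log(x + 50) scale
response: fec1
fixed: [byr.flk.sex]
random:
  animal: {group_by: [animal], covariance: pedigree}
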