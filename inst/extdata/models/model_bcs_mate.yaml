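# Adult ewe body condition score at mating, 1-5 in 0.5 units
response: bcs_mate
fixed: [rflk.ryr.mob.ageclass.2yo_rc, nlb_prev, brr]
random:
  animal: {group_by: [animal], covariance: pedigree}
  wgpe:   {group_by: [animal], covariance: identity}
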