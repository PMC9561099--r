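# Adult ewe live weight at mating, kg
response: lw_mate
fixed: [rflk.ryr.mob.ageclass.2yo_rc, nlb_prev, aod, brr]
random:
  animal: {group_by: [animal], covariance: pedigree}
  wgpe:   {group_by: [animal], covariance: identity}
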