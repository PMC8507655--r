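# Illustrative cancer-risk benchmark table for the synthetic demo.
# Benchmarks are the concentrations corresponding to 1e-6 lifetime cancer
# risk. These values are placeholders for demonstration only, NOT
# regulatory or published health-guideline values; real analyses must
# supply their own table.
contaminants:
  - {id: ARSENIC, benchmark: 0.004, unit: ug/L, mcl: 10}
  - {id: THM4, benchmark: 0.15, unit: ug/L}
  - {id: HAA5, benchmark: 0.1, unit: ug/L, mcl: 60}
  - {id: HAA9, benchmark: 0.06, unit: ug/L}
group_rules:
  haa9_id: HAA9
  haa9_supersedes: HAA5
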