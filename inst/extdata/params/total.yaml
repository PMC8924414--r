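# KEYNOTE-181 total population: second-line pembrolizumab vs investigator's
# choice chemotherapy for advanced/metastatic esophageal cancer.
# Monthly transition probabilities calibrated to the trial's OS/PFS curves;
# monthly costs in 2021 USD (6.4831 CNY/USD), 2021 West China Hospital fees.
schema_version: 1
subgroup: total
model:
  cycle_length_months: 1
  horizon_cycles: 60
  annual_discount_rate: 0.03
  discount_compounding: compound
  half_cycle_correction: true
  wtp_usd_per_qaly: 11105.8
  cny_per_usd: 6.4831
utilities:
  pfs: 0.75
  pd: 0.67
transitions:
  pembrolizumab: {pfs_pfs: 0.781, pfs_pd: 0.130, pfs_death: 0.089, pd_pd: 0.900, pd_death: 0.100}
  chemotherapy:  {pfs_pfs: 0.812, pfs_pd: 0.124, pfs_death: 0.064, pd_pd: 0.806, pd_death: 0.194}
costs:
  pembrolizumab: {drug: 7370.14, tests: 916.94, ae: 12.23, subsequent: 150.14}
  chemotherapy:  {drug: 2231.66, tests: 727.18, ae: 131.79, subsequent: 150.14}
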