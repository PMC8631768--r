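# Demo configuration of the VPD limitation-analysis pipeline.
# Keys mirror the arguments of vpdlim::pipeline_config(); anything omitted
# takes the documented default.
regimes: [HVPD, LVPD]
cultivar: CV1
vpd_grid: [0.5, 1.5, 2.5, 3.5, 4.5]
n_rep: 4
noise: true
noise_cv:
  pn: 0.02
  gsw: 0.05
seed: 1
digits: 6
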