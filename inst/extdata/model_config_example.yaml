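# Example model-structure configuration consumed by read_model_config().
# Unlisted processes keep the package default kinetics and bounds.
processes:
  O_NH4:   {active: true, kinetics: first, bounds: {k: [0, 10]}}
  O_Nrec:  {active: true, kinetics: zero,  bounds: {k: [0, 5]}}
  D_NO3:   {active: true, kinetics: first}
  A_NH4:   {active: true, kinetics: first}
n_lab0:    {bounds: [0, 200]}
design:
  amendment_nh4: 20
  amendment_no3: 20
  enrichment_nh4: 9.44
  enrichment_no3: 9.75
  replicates: 3
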