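coral_reef:
  - coral reef
  - coral reefs
kelp_forest:
  - kelp forest
  - kelp forests
mangrove_forest:
  - mangrove forest
  - mangrove forests
seagrass_bed:
  - seagrass bed
  - seagrass beds
  - seagrass meadow
  - seagrass meadows
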