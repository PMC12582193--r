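{
  "comment": "Experiment 2 population preset: mask RMS contrast (low 0.07 / medium 0.10 / high 0.13) crossed with biomotion orientation. Depths are the planted group condition means; bCFS levels shift in tandem with mask contrast (medium matches the Experiment 1 grand mean, low/high offset by -2/+2 dB as a package choice consistent with the reported ordering).",
  "conditions": {
    "LowUp":   {"bcfs_db": -12.4, "depth_db": 13.07},
    "LowInv":  {"bcfs_db": -12.4, "depth_db": 12.85},
    "MedUp":   {"bcfs_db": -10.4, "depth_db": 13.07},
    "MedInv":  {"bcfs_db": -10.4, "depth_db": 13.18},
    "HighUp":  {"bcfs_db": -8.4,  "depth_db": 12.87},
    "HighInv": {"bcfs_db": -8.4,  "depth_db": 12.93}
  },
  "sd_bcfs_db": 3.0,
  "sd_depth_db": 3.6,
  "jitter_sd_db": 1.0,
  "lapse_prob": 0,
  "delay_frames": 0,
  "empirical": true
}
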