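{
  "comment": "Experiment 3 population preset: profile walker at three speeds plus coherent and temporally scrambled optic flow. Depths are the planted group condition means; bCFS levels follow the reported ordering (moving biomotion lowest, static highest) with magnitudes chosen by the package.",
  "conditions": {
    "FastBM":   {"bcfs_db": -12.0, "depth_db": 12.11},
    "NormalBM": {"bcfs_db": -11.5, "depth_db": 13.19},
    "Static":   {"bcfs_db": -8.5,  "depth_db": 12.48},
    "CoherOF":  {"bcfs_db": -10.0, "depth_db": 13.42},
    "TempOF":   {"bcfs_db": -10.5, "depth_db": 13.53}
  },
  "sd_bcfs_db": 3.0,
  "sd_depth_db": 2.9,
  "jitter_sd_db": 1.0,
  "lapse_prob": 0,
  "delay_frames": 0,
  "empirical": true
}
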