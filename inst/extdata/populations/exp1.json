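{
  "comment": "Experiment 1 population preset: four biomotion targets, planted group condition means. bCFS levels are the grand breakthrough mean (no significant condition differences on bCFS); depths differ by condition.",
  "conditions": {
    "Upright":  {"bcfs_db": -10.4, "depth_db": 13.22},
    "Inverted": {"bcfs_db": -10.4, "depth_db": 13.23},
    "TempScr":  {"bcfs_db": -10.4, "depth_db": 13.24},
    "SpatScr":  {"bcfs_db": -10.4, "depth_db": 13.95}
  },
  "sd_bcfs_db": 3.0,
  "sd_depth_db": 1.5,
  "jitter_sd_db": 1.0,
  "lapse_prob": 0,
  "delay_frames": 0,
  "empirical": true
}
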