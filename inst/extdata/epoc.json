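{
  "name": "EPOC",
  "channel_labels": ["AF3", "F7", "F3", "FC5", "T7", "P7", "O1", "O2", "P8", "T8", "FC6", "F4", "F8", "AF4"],
  "reference_labels": ["P3", "P4"],
  "internal_rate_hz": 2048,
  "output_rate_hz": 128,
  "lsb_uV": 0.51,
  "resolution_bits": 14,
  "bandwidth_hz": [0.16, 43],
  "notch_hz": [50, 60],
  "dynamic_range_uVpp": 8400
}
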