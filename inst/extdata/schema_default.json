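{
  "time": "time",
  "left_x": "left_x",
  "left_y": "left_y",
  "right_x": "right_x",
  "right_y": "right_y",
  "left_valid": "left_valid",
  "right_valid": "right_valid",
  "pupil_left": "pupil_left",
  "pupil_right": "pupil_right"
}
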