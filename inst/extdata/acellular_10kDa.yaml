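# 10 kDa FITC-dextran acellular (scaffold-only) run
geometry:
  apical_width: "200 um"
  channel_height: "100 um"
  chamber_diameter: "1800 um"
tracer:
  preset: "10kDa"
transport:
  acellular: true
  p_scaffold: 5.0e-5         # cm/s
  apical_fill_tau: "300 s"
acquisition:
  frame_interval: "60 s"
  n_frames: 120
analysis: {}
seeds: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
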