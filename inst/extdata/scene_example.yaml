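# Example configuration: override any field of the virtual scene geometry.
# Omitted fields keep their defaults (see ?scene_geometry).
scene:
  release_height: 9.72
  ring_height: 0.775
  ball_diameter: 0.07
  eye_ring_offset: 0.5
  g: 9.8
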