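# Landmark index map for the 66-point annotation (0-based indices,
# matching the landmark CSV header x0..x65). Copy and edit this file to
# adapt the geometric features to a tracker with different indexing, then
# load it with read_index_map().
visual:
  index_map:
    outer_eyebrow_height: {upper: [17, 26], lower: [36, 45]}
    inner_eyebrow_height: {upper: [21, 22], lower: [39, 42]}
    outer_lip_height:     {upper: [50, 51, 52], lower: [56, 57, 58]}
    inner_lip_height:     {upper: [60, 61, 62], lower: [63, 64, 65]}
    eye_opening:          {upper: [37, 38, 43, 44], lower: [40, 41, 46, 47]}
    lip_corner_distance:  {points: [48, 54]}
    eye_centers:
      left:  [36, 37, 38, 39, 40, 41]
      right: [42, 43, 44, 45, 46, 47]
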