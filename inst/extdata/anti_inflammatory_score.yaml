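# Default anti-inflammatory score definition: eleven items scored 1 at
# high consumption. Frequency items use the seven-point scale codes
# 0=never .. 6=daily; min_level is the lowest qualifying code.
green_leafy:
  kind: frequency
  min_level: 4
salad:
  kind: frequency
  min_level: 4
veg_general:
  kind: frequency
  min_level: 5
citrus:
  kind: frequency
  min_level: 5
fruits:
  kind: frequency
  min_level: 6
coffee:
  kind: frequency
  min_level: 6
nuts:
  kind: frequency
  min_level: 3
fish_n3:
  kind: frequency
  min_level: 3
olive_oil:
  kind: binary
rosemary:
  kind: binary
salvia:
  kind: binary
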