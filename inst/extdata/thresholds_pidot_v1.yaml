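# Canonical "pidot-v1" threshold set for the manual gating engine.
#
# Per marker: the three ordered cut points (neg|lo, lo|pos, pos|hi) on the
# asinh-transformed scale. Cut points sit in the low-density valleys between
# the bands that are actually occupied on each marker in normal samples,
# which is where an expert places a gate. On markers where the lo band is
# unoccupied the valley spans 0 to 3 and the neg|lo and lo|pos cuts bracket
# its center; CD27, whose lo band is occupied (CD8+ effector CD27+ cells),
# uses an asymmetric lo|pos cut of 2.0 so that the far more abundant
# CD27+ naive/memory subsets do not spill into the sparse lo band.
cuts:
  CD45:      [0.75, 2.25, 3.20]
  CD3:       [1.40, 1.60, 3.75]
  CD19:      [1.40, 1.60, 3.75]
  "CD16&CD56": [0.75, 2.25, 3.00]
  CD4:       [1.40, 1.60, 3.75]
  CD8:       [1.40, 1.60, 3.75]
  TCRgd:     [1.40, 1.60, 3.75]
  CD27:      [0.75, 2.00, 3.75]
  CD45RA:    [1.40, 1.60, 3.75]
  IgM:       [1.40, 1.60, 3.75]
  IgD:       [1.40, 1.60, 3.75]
# Lymphocyte scatter rectangle (raw channel units) and the FSC-A floor
# below which events count as debris.
scatter_gate:
  fsc_a: [30000, 85000]
  ssc_a: [0, 25000]
debris_fsc_max: 30000
# Kept singlets satisfy |FSC-H/FSC-A / median ratio - 1| <= tolerance.
doublet_ratio_tolerance: 0.25
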