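# Shipped population registry for the PIDOT-like panel ("pidot-v1").
#
# Band levels use the four-level convention neg / lo / pos / hi realized by
# the band model (generator means 0 / 1.5 / 3.0 / 4.5 on the asinh scale).
# fraction_range entries are order-of-magnitude plausible adult healthy-donor
# frequencies expressed as fractions of all white blood cells; they are
# generator inputs, not population claims. Scatter means are FSC-A / SSC-A
# channel units centered in the recommended lymphocyte QC intervals.
markers: [CD45, CD3, CD19, "CD16&CD56", CD4, CD8, TCRgd, CD27, CD45RA, IgM, IgD]
scatter_sd:
  lymphoid: [4000, 1200]
  debris: [3000, 1500]
  other_leukocyte: [15000, 10000]
populations:
  - id: lymphocytes
    label: "Lymphocytes"
    parent: ~
  - id: b_cells
    label: "B-cells"
    parent: lymphocytes
  - id: pre_gc_b
    label: "Pre-germinal center B-cells"
    parent: b_cells
    bands: {CD45: hi, CD3: neg, CD19: pos, "CD16&CD56": neg, CD4: neg, CD8: neg,
            TCRgd: neg, CD27: neg, CD45RA: pos, IgM: pos, IgD: pos}
    scatter_mean: [55000, 12000]
    fraction_range: [0.020, 0.030]
  - id: unswitched_mbc_pc
    label: "Unswitched MBC/PC"
    parent: b_cells
    bands: {CD45: hi, CD3: neg, CD19: pos, "CD16&CD56": neg, CD4: neg, CD8: neg,
            TCRgd: neg, CD27: pos, CD45RA: pos, IgM: pos, IgD: pos}
    scatter_mean: [55000, 12000]
    fraction_range: [0.004, 0.008]
  - id: switched_mbc_pc
    label: "Switched MBC/PC"
    parent: b_cells
    bands: {CD45: hi, CD3: neg, CD19: pos, "CD16&CD56": neg, CD4: neg, CD8: neg,
            TCRgd: neg, CD27: pos, CD45RA: pos, IgM: neg, IgD: neg}
    scatter_mean: [55000, 12000]
    fraction_range: [0.004, 0.008]
  - id: igd_only_post_gc
    label: "IgD+IgM- post-GC B-cells"
    parent: b_cells
    bands: {CD45: hi, CD3: neg, CD19: pos, "CD16&CD56": neg, CD4: neg, CD8: neg,
            TCRgd: neg, CD27: pos, CD45RA: pos, IgM: neg, IgD: pos}
    scatter_mean: [55000, 12000]
    fraction_range: [0.0008, 0.002]
  - id: t_cells
    label: "T-cells"
    parent: lymphocytes
  - id: tcr_gd_t
    label: "TCRgd+ T-cells"
    parent: t_cells
    bands: {CD45: hi, CD3: pos, CD19: neg, "CD16&CD56": neg, CD4: neg, CD8: neg,
            TCRgd: pos, CD27: pos, CD45RA: pos, IgM: neg, IgD: neg}
    scatter_mean: [55000, 12000]
    fraction_range: [0.008, 0.015]
  - id: dn_t
    label: "CD4-CD8- TCRgd- T-cells"
    parent: t_cells
    bands: {CD45: hi, CD3: pos, CD19: neg, "CD16&CD56": neg, CD4: neg, CD8: neg,
            TCRgd: neg, CD27: pos, CD45RA: pos, IgM: neg, IgD: neg}
    scatter_mean: [55000, 12000]
    fraction_range: [0.003, 0.006]
  - id: cd4_t
    label: "CD4+ T-cells"
    parent: t_cells
  - id: cd4_naive
    label: "CD4+ naive T-cells"
    parent: cd4_t
    bands: {CD45: hi, CD3: pos, CD19: neg, "CD16&CD56": neg, CD4: pos, CD8: neg,
            TCRgd: neg, CD27: pos, CD45RA: pos, IgM: neg, IgD: neg}
    scatter_mean: [55000, 12000]
    fraction_range: [0.060, 0.090]
  - id: cd4_cm
    label: "CD4+ central memory T-cells"
    parent: cd4_t
    bands: {CD45: hi, CD3: pos, CD19: neg, "CD16&CD56": neg, CD4: pos, CD8: neg,
            TCRgd: neg, CD27: pos, CD45RA: neg, IgM: neg, IgD: neg}
    scatter_mean: [55000, 12000]
    fraction_range: [0.040, 0.060]
  - id: cd4_em
    label: "CD4+ effector memory T-cells"
    parent: cd4_t
    bands: {CD45: hi, CD3: pos, CD19: neg, "CD16&CD56": neg, CD4: pos, CD8: neg,
            TCRgd: neg, CD27: neg, CD45RA: neg, IgM: neg, IgD: neg}
    scatter_mean: [55000, 12000]
    fraction_range: [0.010, 0.020]
  - id: cd4_td
    label: "CD4+ terminal effector T-cells"
    parent: cd4_t
    bands: {CD45: hi, CD3: pos, CD19: neg, "CD16&CD56": neg, CD4: pos, CD8: neg,
            TCRgd: neg, CD27: neg, CD45RA: pos, IgM: neg, IgD: neg}
    scatter_mean: [55000, 12000]
    fraction_range: [0.002, 0.005]
  - id: cd8_t
    label: "CD8+ T-cells"
    parent: t_cells
  - id: cd8_naive
    label: "CD8+ naive T-cells"
    parent: cd8_t
    bands: {CD45: hi, CD3: pos, CD19: neg, "CD16&CD56": neg, CD4: neg, CD8: pos,
            TCRgd: neg, CD27: pos, CD45RA: pos, IgM: neg, IgD: neg}
    scatter_mean: [55000, 12000]
    fraction_range: [0.030, 0.045]
  - id: cd8_cm
    label: "CD8+ central memory T-cells"
    parent: cd8_t
    bands: {CD45: hi, CD3: pos, CD19: neg, "CD16&CD56": neg, CD4: neg, CD8: pos,
            TCRgd: neg, CD27: pos, CD45RA: neg, IgM: neg, IgD: neg}
    scatter_mean: [55000, 12000]
    fraction_range: [0.008, 0.015]
  - id: cd8_em
    label: "CD8+ effector memory T-cells"
    parent: cd8_t
    bands: {CD45: hi, CD3: pos, CD19: neg, "CD16&CD56": neg, CD4: neg, CD8: pos,
            TCRgd: neg, CD27: neg, CD45RA: neg, IgM: neg, IgD: neg}
    scatter_mean: [55000, 12000]
    fraction_range: [0.006, 0.012]
  - id: cd8_td27pos
    label: "CD8+ effector CD27+ T-cells"
    parent: cd8_t
    bands: {CD45: hi, CD3: pos, CD19: neg, "CD16&CD56": neg, CD4: neg, CD8: pos,
            TCRgd: neg, CD27: lo, CD45RA: pos, IgM: neg, IgD: neg}
    scatter_mean: [55000, 12000]
    fraction_range: [0.001, 0.004]
  - id: cd8_td27neg
    label: "CD8+ terminal effector T-cells"
    parent: cd8_t
    bands: {CD45: hi, CD3: pos, CD19: neg, "CD16&CD56": neg, CD4: neg, CD8: pos,
            TCRgd: neg, CD27: neg, CD45RA: pos, IgM: neg, IgD: neg}
    scatter_mean: [55000, 12000]
    fraction_range: [0.004, 0.009]
  - id: dp_t
    label: "CD4+CD8+ T-cells"
    parent: t_cells
    bands: {CD45: hi, CD3: pos, CD19: neg, "CD16&CD56": neg, CD4: pos, CD8: pos,
            TCRgd: neg, CD27: pos, CD45RA: pos, IgM: neg, IgD: neg}
    scatter_mean: [55000, 12000]
    fraction_range: [0.0005, 0.0015]
  - id: nk_cells
    label: "Natural Killer cells"
    parent: lymphocytes
    bands: {CD45: hi, CD3: neg, CD19: neg, "CD16&CD56": hi, CD4: neg, CD8: neg,
            TCRgd: neg, CD27: neg, CD45RA: pos, IgM: neg, IgD: neg}
    scatter_mean: [55000, 12000]
    fraction_range: [0.025, 0.045]
  - id: other_leukocyte
    label: "Other leukocytes"
    parent: ~
    bands: {CD45: pos, CD3: neg, CD19: neg, "CD16&CD56": neg, CD4: neg, CD8: neg,
            TCRgd: neg, CD27: neg, CD45RA: neg, IgM: neg, IgD: neg}
    scatter_mean: [120000, 60000]
  - id: debris
    label: "Debris"
    parent: ~
    bands: {CD45: neg, CD3: neg, CD19: neg, "CD16&CD56": neg, CD4: neg, CD8: neg,
            TCRgd: neg, CD27: neg, CD45RA: neg, IgM: neg, IgD: neg}
    scatter_mean: [8000, 3000]
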