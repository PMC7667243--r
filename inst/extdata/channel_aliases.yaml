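# Map of observed channel spellings -> canonical panel short names.
# Extend locally and pass through channel_aliases(path = ...).
"FSC-Area": "FSC-A"
"FSC-Height": "FSC-H"
"SSC-Area": "SSC-A"
"FSC.A": "FSC-A"
"FSC.H": "FSC-H"
"SSC.A": "SSC-A"
"CD56 CD16": "CD16&CD56"
"CD16 CD56": "CD16&CD56"
"CD16+CD56": "CD16&CD56"
"CD16_CD56": "CD16&CD56"
"CD16.CD56": "CD16&CD56"
"TCRgd": "TCRgd"
"TCR gamma delta": "TCRgd"
"TCRganmadelta": "TCRgd"
"TCRyd": "TCRgd"
"IgM": "IgM"
"IgD": "IgD"
"sIgM": "IgM"
"sIgD": "IgD"
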