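# Switch-II pocket residue lists for KRAS G12C covalent docking
# (chain A, author numbering). The reactive residue is Cys12; blocking
# residues are the subset of flexible residues mutated to alanine before
# the initial docking stage.
reactive: A:12
flexible:
- A:58
- A:59
- A:60
- A:61
- A:62
- A:63
- A:64
- A:65
- A:66
- A:67
- A:68
- A:69
- A:70
- A:71
- A:72
- A:73
- A:74
- A:88
- A:92
- A:95
- A:96
- A:99
- A:102
- A:103
- A:12
- A:37
blocking:
- A:62
- A:64
- A:68
- A:72
- A:95
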