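# "provirus" preset: one phage-like viral profile and one host-like
# non-viral profile with well-separated statistics, for host-viral-host
# integration fixtures with known boundaries.
name: provirus
viral:
  dsDNAphage:
    gene_len: [600, 180]
    gene_density: 1.35
    genome_len: [25000, 70000]
    p_category: {viral: 0.55, archaeal: 0.01, bacterial: 0.03, eukaryotic: 0.01, mixed: 0.05, unaligned: 0.35}
    p_hallmark: 0.15
    p_strand_switch: 0.05
    p_overlap: 0.18
    start_codon: {ATG: 0.80, GTG: 0.10, TTG: 0.08, other: 0.02}
    gc: [0.42, 0.03]
    rbs: {SD_Canonical: 0.10, SD_Bacteroidetes: 0.02, TATATA_3-6: 0.08, OnlyA: 0.05, OnlyT: 0.05, DoubleA: 0.04, DoubleT: 0.03, Other_GA: 0.03, NoA: 0.03, Other: 0.02, None: 0.55}
    bit_score: [80, 25]
nonviral:
  prokaryote:
    gene_len: [900, 300]
    gene_density: 1.00
    genome_len: [40000, 120000]
    p_category: {viral: 0.04, archaeal: 0.05, bacterial: 0.50, eukaryotic: 0.01, mixed: 0.15, unaligned: 0.25}
    p_hallmark: 0.0
    p_strand_switch: 0.30
    p_overlap: 0.05
    start_codon: {ATG: 0.75, GTG: 0.14, TTG: 0.09, other: 0.02}
    gc: [0.52, 0.05]
    rbs: {SD_Canonical: 0.50, SD_Bacteroidetes: 0.08, TATATA_3-6: 0.02, OnlyA: 0.05, OnlyT: 0.03, DoubleA: 0.04, DoubleT: 0.03, Other_GA: 0.06, NoA: 0.04, Other: 0.03, None: 0.12}
    bit_score: [85, 30]
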