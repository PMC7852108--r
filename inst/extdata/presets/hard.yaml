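# "hard" preset: overlapping viral vs non-viral statistics. Viral profiles
# carry fewer viral-annotated genes and more cellular annotation; non-viral
# profiles gain viral-annotated genes and calmer gene architecture. Used to
# probe classifier behaviour when class separation is weak.
name: hard
viral:
  dsDNAphage:
    gene_len: [700, 220]
    gene_density: 1.15
    genome_len: [25000, 70000]
    p_category: {viral: 0.30, archaeal: 0.01, bacterial: 0.12, eukaryotic: 0.01, mixed: 0.10, unaligned: 0.46}
    p_hallmark: 0.06
    p_strand_switch: 0.15
    p_overlap: 0.10
    start_codon: {ATG: 0.78, GTG: 0.12, TTG: 0.08, other: 0.02}
    gc: [0.46, 0.05]
    rbs: {SD_Canonical: 0.25, SD_Bacteroidetes: 0.04, TATATA_3-6: 0.04, OnlyA: 0.05, OnlyT: 0.04, DoubleA: 0.04, DoubleT: 0.03, Other_GA: 0.06, NoA: 0.05, Other: 0.05, None: 0.35}
    bit_score: [75, 30]
  NCLDV:
    gene_len: [900, 300]
    gene_density: 0.80
    genome_len: [80000, 160000]
    p_category: {viral: 0.25, archaeal: 0.01, bacterial: 0.05, eukaryotic: 0.20, mixed: 0.12, unaligned: 0.37}
    p_hallmark: 0.04
    p_strand_switch: 0.20
    p_overlap: 0.04
    start_codon: {ATG: 0.86, GTG: 0.05, TTG: 0.04, other: 0.05}
    gc: [0.42, 0.05]
    rbs: {SD_Canonical: 0.08, SD_Bacteroidetes: 0.03, TATATA_3-6: 0.04, OnlyA: 0.04, OnlyT: 0.03, DoubleA: 0.03, DoubleT: 0.02, Other_GA: 0.03, NoA: 0.02, Other: 0.08, None: 0.60}
    bit_score: [65, 25]
  RNA:
    gene_len: [1000, 400]
    gene_density: 0.80
    genome_len: [3000, 12000]
    p_category: {viral: 0.28, archaeal: 0.01, bacterial: 0.04, eukaryotic: 0.05, mixed: 0.08, unaligned: 0.54}
    p_hallmark: 0.10
    p_strand_switch: 0.08
    p_overlap: 0.08
    start_codon: {ATG: 0.88, GTG: 0.05, TTG: 0.03, other: 0.04}
    gc: [0.46, 0.06]
    rbs: {SD_Canonical: 0.06, SD_Bacteroidetes: 0.02, TATATA_3-6: 0.03, OnlyA: 0.04, OnlyT: 0.03, DoubleA: 0.03, DoubleT: 0.02, Other_GA: 0.02, NoA: 0.02, Other: 0.03, None: 0.70}
    bit_score: [60, 20]
  ssDNA:
    gene_len: [550, 180]
    gene_density: 1.05
    genome_len: [1500, 8000]
    p_category: {viral: 0.28, archaeal: 0.01, bacterial: 0.10, eukaryotic: 0.02, mixed: 0.10, unaligned: 0.49}
    p_hallmark: 0.12
    p_strand_switch: 0.20
    p_overlap: 0.08
    start_codon: {ATG: 0.82, GTG: 0.09, TTG: 0.06, other: 0.03}
    gc: [0.47, 0.05]
    rbs: {SD_Canonical: 0.20, SD_Bacteroidetes: 0.04, TATATA_3-6: 0.06, OnlyA: 0.06, OnlyT: 0.04, DoubleA: 0.04, DoubleT: 0.03, Other_GA: 0.05, NoA: 0.04, Other: 0.04, None: 0.40}
    bit_score: [55, 20]
  lavidaviridae:
    gene_len: [700, 230]
    gene_density: 1.05
    genome_len: [15000, 30000]
    p_category: {viral: 0.26, archaeal: 0.01, bacterial: 0.10, eukaryotic: 0.04, mixed: 0.10, unaligned: 0.49}
    p_hallmark: 0.05
    p_strand_switch: 0.16
    p_overlap: 0.08
    start_codon: {ATG: 0.80, GTG: 0.10, TTG: 0.06, other: 0.04}
    gc: [0.40, 0.05]
    rbs: {SD_Canonical: 0.18, SD_Bacteroidetes: 0.03, TATATA_3-6: 0.04, OnlyA: 0.06, OnlyT: 0.04, DoubleA: 0.04, DoubleT: 0.03, Other_GA: 0.05, NoA: 0.04, Other: 0.04, None: 0.45}
    bit_score: [60, 20]
nonviral:
  prokaryote:
    gene_len: [850, 280]
    gene_density: 1.05
    genome_len: [40000, 120000]
    p_category: {viral: 0.10, archaeal: 0.04, bacterial: 0.35, eukaryotic: 0.01, mixed: 0.18, unaligned: 0.32}
    p_hallmark: 0.0
    p_strand_switch: 0.22
    p_overlap: 0.06
    start_codon: {ATG: 0.76, GTG: 0.13, TTG: 0.09, other: 0.02}
    gc: [0.48, 0.05]
    rbs: {SD_Canonical: 0.35, SD_Bacteroidetes: 0.06, TATATA_3-6: 0.03, OnlyA: 0.05, OnlyT: 0.03, DoubleA: 0.04, DoubleT: 0.03, Other_GA: 0.07, NoA: 0.05, Other: 0.04, None: 0.25}
    bit_score: [80, 30]
  eukaryote:
    gene_len: [1200, 420]
    gene_density: 0.65
    genome_len: [30000, 100000]
    p_category: {viral: 0.06, archaeal: 0.01, bacterial: 0.06, eukaryotic: 0.30, mixed: 0.20, unaligned: 0.37}
    p_hallmark: 0.0
    p_strand_switch: 0.35
    p_overlap: 0.03
    start_codon: {ATG: 0.90, GTG: 0.03, TTG: 0.02, other: 0.05}
    gc: [0.45, 0.06]
    rbs: {SD_Canonical: 0.03, SD_Bacteroidetes: 0.01, TATATA_3-6: 0.03, OnlyA: 0.03, OnlyT: 0.02, DoubleA: 0.02, DoubleT: 0.01, Other_GA: 0.02, NoA: 0.02, Other: 0.06, None: 0.75}
    bit_score: [70, 25]
  plasmid:
    gene_len: [800, 280]
    gene_density: 1.00
    genome_len: [5000, 40000]
    p_category: {viral: 0.12, archaeal: 0.02, bacterial: 0.28, eukaryotic: 0.02, mixed: 0.22, unaligned: 0.34}
    p_hallmark: 0.0
    p_strand_switch: 0.18
    p_overlap: 0.08
    start_codon: {ATG: 0.79, GTG: 0.11, TTG: 0.08, other: 0.02}
    gc: [0.49, 0.05]
    rbs: {SD_Canonical: 0.30, SD_Bacteroidetes: 0.05, TATATA_3-6: 0.03, OnlyA: 0.05, OnlyT: 0.04, DoubleA: 0.04, DoubleT: 0.03, Other_GA: 0.07, NoA: 0.05, Other: 0.06, None: 0.28}
    bit_score: [70, 25]
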