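# "easy" preset: well-separated viral vs non-viral annotation statistics.
# Viral profiles: high % of viral-annotated and unaligned genes, hallmark
# genes present, low strand switching, RBS mostly absent. Non-viral
# profiles: high % of cellular-annotated genes, frequent strand switching,
# Shine-Dalgarno RBS common (prokaryote/plasmid). gene_len/gc/bit_score are
# [mean, sd]; genome_len is [min, max] bp.
name: easy
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
  NCLDV:
    gene_len: [800, 250]
    gene_density: 0.95
    genome_len: [80000, 160000]
    p_category: {viral: 0.45, archaeal: 0.01, bacterial: 0.02, eukaryotic: 0.08, mixed: 0.06, unaligned: 0.38}
    p_hallmark: 0.08
    p_strand_switch: 0.10
    p_overlap: 0.05
    start_codon: {ATG: 0.85, GTG: 0.06, TTG: 0.05, other: 0.04}
    gc: [0.36, 0.04]
    rbs: {SD_Canonical: 0.03, SD_Bacteroidetes: 0.01, TATATA_3-6: 0.05, OnlyA: 0.04, OnlyT: 0.03, DoubleA: 0.02, DoubleT: 0.01, Other_GA: 0.01, NoA: 0.01, Other: 0.04, None: 0.75}
    bit_score: [70, 25]
  RNA:
    gene_len: [900, 350]
    gene_density: 0.90
    genome_len: [3000, 12000]
    p_category: {viral: 0.50, archaeal: 0.005, bacterial: 0.01, eukaryotic: 0.015, mixed: 0.03, unaligned: 0.44}
    p_hallmark: 0.20
    p_strand_switch: 0.03
    p_overlap: 0.10
    start_codon: {ATG: 0.90, GTG: 0.04, TTG: 0.03, other: 0.03}
    gc: [0.45, 0.05]
    rbs: {SD_Canonical: 0.02, SD_Bacteroidetes: 0.01, TATATA_3-6: 0.04, OnlyA: 0.03, OnlyT: 0.03, DoubleA: 0.02, DoubleT: 0.01, Other_GA: 0.01, NoA: 0.01, Other: 0.02, None: 0.80}
    bit_score: [65, 20]
  ssDNA:
    gene_len: [500, 150]
    gene_density: 1.10
    genome_len: [1500, 8000]
    p_category: {viral: 0.50, archaeal: 0.01, bacterial: 0.03, eukaryotic: 0.01, mixed: 0.05, unaligned: 0.40}
    p_hallmark: 0.25
    p_strand_switch: 0.15
    p_overlap: 0.10
    start_codon: {ATG: 0.85, GTG: 0.07, TTG: 0.05, other: 0.03}
    gc: [0.44, 0.04]
    rbs: {SD_Canonical: 0.06, SD_Bacteroidetes: 0.02, TATATA_3-6: 0.10, OnlyA: 0.06, OnlyT: 0.04, DoubleA: 0.03, DoubleT: 0.02, Other_GA: 0.02, NoA: 0.02, Other: 0.03, None: 0.60}
    bit_score: [60, 20]
  lavidaviridae:
    gene_len: [650, 200]
    gene_density: 1.20
    genome_len: [15000, 30000]
    p_category: {viral: 0.48, archaeal: 0.01, bacterial: 0.04, eukaryotic: 0.02, mixed: 0.05, unaligned: 0.40}
    p_hallmark: 0.12
    p_strand_switch: 0.08
    p_overlap: 0.12
    start_codon: {ATG: 0.82, GTG: 0.08, TTG: 0.06, other: 0.04}
    gc: [0.33, 0.04]
    rbs: {SD_Canonical: 0.05, SD_Bacteroidetes: 0.02, TATATA_3-6: 0.06, OnlyA: 0.05, OnlyT: 0.04, DoubleA: 0.03, DoubleT: 0.02, Other_GA: 0.03, NoA: 0.02, Other: 0.03, None: 0.65}
    bit_score: [65, 20]
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
  eukaryote:
    gene_len: [1300, 450]
    gene_density: 0.55
    genome_len: [30000, 100000]
    p_category: {viral: 0.02, archaeal: 0.01, bacterial: 0.04, eukaryotic: 0.45, mixed: 0.18, unaligned: 0.30}
    p_hallmark: 0.0
    p_strand_switch: 0.45
    p_overlap: 0.02
    start_codon: {ATG: 0.92, GTG: 0.02, TTG: 0.01, other: 0.05}
    gc: [0.46, 0.06]
    rbs: {SD_Canonical: 0.01, SD_Bacteroidetes: 0.01, TATATA_3-6: 0.02, OnlyA: 0.02, OnlyT: 0.01, DoubleA: 0.01, DoubleT: 0.005, Other_GA: 0.005, NoA: 0.01, Other: 0.05, None: 0.85}
    bit_score: [75, 25]
  plasmid:
    gene_len: [850, 300]
    gene_density: 0.95
    genome_len: [5000, 40000]
    p_category: {viral: 0.06, archaeal: 0.02, bacterial: 0.38, eukaryotic: 0.02, mixed: 0.20, unaligned: 0.32}
    p_hallmark: 0.0
    p_strand_switch: 0.25
    p_overlap: 0.06
    start_codon: {ATG: 0.78, GTG: 0.12, TTG: 0.08, other: 0.02}
    gc: [0.50, 0.05]
    rbs: {SD_Canonical: 0.40, SD_Bacteroidetes: 0.06, TATATA_3-6: 0.02, OnlyA: 0.05, OnlyT: 0.04, DoubleA: 0.04, DoubleT: 0.03, Other_GA: 0.07, NoA: 0.05, Other: 0.04, None: 0.20}
    bit_score: [75, 25]
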