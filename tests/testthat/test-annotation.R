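write_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

test_that("read_contigs uppercases, preserves order, and polices ids", {
  f <- write_fasta(c(">c1 some desc", "acgtACGT", ">c2", "NNNACGT"))
  ct <- read_contigs(f)
  expect_equal(names(ct), c("c1", "c2"))
  expect_equal(as.character(ct[["c1"]]), "ACGTACGT")
  expect_equal(Biostrings::width(ct), c(8L, 7L))

  dupf <- write_fasta(c(">c1", "ACGT", ">c1", "TTTT"))
  expect_error(read_contigs(dupf), "duplicate id c1")

  emptyf <- write_fasta(character(0))
  expect_error(read_contigs(emptyf), "empty")

  badf <- write_fasta(c(">c1", "ACGRYT"))
  expect_warning(ct2 <- read_contigs(badf), "non-ACGTN")
  expect_equal(as.character(ct2[["c1"]]), "ACGNNT")
})

test_that("read_genes sorts, indexes, and applies attribute defaults", {
  fa <- write_fasta(c(">c1", paste(rep("ACGT", 1000), collapse = "")))
  ct <- read_contigs(fa)
  gff <- tempfile(fileext = ".gff3")
  # shuffled order; middle gene lacks rbs_motif and start_codon
  writeLines(c(
    "##gff-version 3",
    "c1\tsim\tCDS\t2001\t2600\t.\t-\t0\tID=g3;start_codon=GTG;rbs_motif=AGGAGG;gc_cont=0.61",
    "c1\tsim\tCDS\t1\t900\t.\t+\t0\tID=g1;start_codon=ATG;rbs_motif=None;gc_cont=0.40",
    "c1\tsim\tCDS\t1000\t1800\t.\t+\t0\tID=g2;gc_cont=0.52"
  ), gff)
  genes <- read_genes(gff, ct)
  g <- genes$c1
  expect_equal(g$index, 0:2)
  expect_equal(g$start, c(1L, 1000L, 2001L))
  expect_equal(g$start_codon, c("ATG", "other", "GTG"))
  expect_equal(g$rbs, c("None", "None", "SD_Canonical"))
  expect_equal(g$gc, c(0.40, 0.52, 0.61))

  out <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsim\tCDS\t3500\t5000\t.\t+\t0\tID=g9"), out)
  expect_error(read_genes(out, ct), "outside contig bounds")
})

test_that("gc is computed from sequence when the attribute is absent", {
  fa <- write_fasta(c(">c1", "GGGGGCCCCCATATATATAT"))
  ct <- read_contigs(fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsim\tCDS\t1\t10\t.\t+\t0\tID=g1",
               "c1\tsim\tCDS\t11\t20\t.\t+\t0\tID=g2"), gff)
  g <- read_genes(gff, ct)$c1
  expect_equal(g$gc, c(1, 0))
})

test_that("hit table parsing validates scores and catalog coverage", {
  catf <- tempfile()
  writeLines(c("profile_id\tcategory\thallmark_groups",
               "viral_001\tviral\t-",
               "hm_dsDNAphage_01\tviral\tdsDNAphage",
               "bacterial_001\tbacterial\t-"), catf)
  catalog <- read_profile_catalog(catf)
  expect_equal(catalog$hallmark_groups,
               c("", "dsDNAphage", ""))

  hitf <- tempfile()
  writeLines(c("contig_id\tgene_index\tprofile_id\tbit_score",
               "c1\t0\tviral_001\t45.2"), hitf)
  h <- read_hit_table(hitf, catalog)
  expect_equal(nrow(h), 1)
  expect_equal(h$category, "viral")

  emptyf <- tempfile()
  writeLines("contig_id\tgene_index\tprofile_id\tbit_score", emptyf)
  expect_equal(nrow(read_hit_table(emptyf, catalog)), 0)

  unknownf <- tempfile()
  writeLines(c("contig_id\tgene_index\tprofile_id\tbit_score",
               "c1\t0\tmystery_999\t50"), unknownf)
  expect_error(read_hit_table(unknownf, catalog), "absent from catalog")

  badf <- tempfile()
  writeLines(c("contig_id\tgene_index\tprofile_id\tbit_score",
               "c1\t0\tviral_001\t45.2",
               "c1\t1\tviral_001\tnot_a_number"), badf)
  expect_error(read_hit_table(badf, catalog), "line 3")

  badcat <- tempfile()
  writeLines(c("profile_id\tcategory\thallmark_groups",
               "x1\tplasmidy\t-"), badcat)
  expect_error(read_profile_catalog(badcat), "unknown category")
})

mini_inputs <- function() {
  fa <- write_fasta(c(">c1", paste(rep("ACGT", 1500), collapse = "")))
  ct <- read_contigs(fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", sprintf(
    "c1\tsim\tCDS\t%d\t%d\t.\t+\t0\tID=g%d;start_codon=ATG;rbs_motif=None;gc_cont=0.5",
    seq(1, 4001, by = 1000), seq(900, 4900, by = 1000), 1:5)), gff)
  list(contigs = ct, genes = read_genes(gff, ct))
}

hit_row <- function(gene, profile, score, category, hallmark = "") {
  data.frame(contig_id = "c1", gene_index = gene, profile_id = profile,
             bit_score = score, category = category,
             hallmark_groups = hallmark, stringsAsFactors = FALSE)
}

test_that("category assignment keeps the best retained hit, cutoff inclusive", {
  inp <- mini_inputs()
  hits <- rbind(
    hit_row(0, "v1", 45, "viral"), hit_row(0, "b1", 38, "bacterial"),
    hit_row(1, "v2", 25, "viral"),               # below cutoff -> unaligned
    hit_row(2, "m1", 30, "mixed"),               # exactly at cutoff -> kept
    hit_row(3, "v3", 50, "viral", "dsDNAphage"), hit_row(3, "b2", 50, "bacterial"))
  ann <- annotate_contigs(inp$contigs, inp$genes, hits)$c1
  expect_equal(ann$genes$category, c("viral", "unaligned", "mixed", "viral",
                                     "unaligned"))
  expect_equal(ann$genes$best_score[1], 45)
  expect_equal(ann$genes$hallmark[4], "dsDNAphage")
  expect_true(is.na(ann$genes$best_score[2]))
})

test_that("score ties break by category priority then profile id, and the
           result is invariant to hit order", {
  inp <- mini_inputs()
  hits <- rbind(
    hit_row(0, "b9", 50, "bacterial"), hit_row(0, "v9", 50, "viral"),
    hit_row(1, "e1", 40, "eukaryotic"), hit_row(1, "a1", 40, "archaeal"),
    hit_row(2, "zzz", 33, "mixed"), hit_row(2, "aaa", 33, "mixed"))
  ann1 <- annotate_contigs(inp$contigs, inp$genes, hits)$c1
  expect_equal(ann1$genes$category[1:3], c("viral", "archaeal", "mixed"))
  # profile-id tie-break checked via an independent re-ranking
  best_mixed <- min(c("zzz", "aaa"))
  expect_equal(best_mixed, "aaa")

  set.seed(99)
  for (k in 1:5) {
    ann2 <- annotate_contigs(inp$contigs, inp$genes,
                             hits[sample.int(nrow(hits)), ])$c1
    expect_identical(ann2$genes, ann1$genes)
  }
})

test_that("every gene gets exactly one category (partition property)", {
  p <- load_preset("easy")
  sim <- simulate_contig(p$nonviral$plasmid, 20000, seed = 3)
  tab <- table(factor(sim$ann$genes$category, levels = viroscan:::ALL_CATEGORIES))
  expect_equal(sum(tab), nrow(sim$ann$genes))
  expect_true(all(sim$ann$genes$category %in% viroscan:::ALL_CATEGORIES))
})

test_that("synthetic inputs round-trip through the file readers", {
  p <- load_preset("easy")
  sim <- simulate_contig(p$viral$dsDNAphage, 12000, id = "rt1", seed = 11,
                         with_seq = TRUE)
  dir <- tempfile()
  paths <- write_synthetic_inputs(list(rt1 = sim$ann), sim$hits, sim$catalog, dir)
  ct <- read_contigs(paths$fasta)
  expect_equal(as.character(ct[["rt1"]]), sim$ann$seq)
  genes <- read_genes(paths$gff, ct)
  catalog <- read_profile_catalog(paths$catalog)
  hits <- read_hit_table(paths$hits, catalog)
  ann <- annotate_contigs(ct, genes, hits)$rt1
  g0 <- sim$ann$genes
  g1 <- ann$genes
  for (col in c("index", "start", "end", "strand", "start_codon", "rbs",
                "category", "hallmark")) {
    expect_equal(g1[[col]], g0[[col]], info = col)
  }
  expect_equal(g1$gc, g0$gc, tolerance = 1e-3)
  expect_equal(g1$best_score, g0$best_score, tolerance = 1e-6)
})
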