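# Seeded synthetic-data generator. Emulates the group-specific statistical
# structure of annotated contigs (gene architecture, per-gene annotation
# categories, hallmark flags, RBS usage, GC) so that training, detection and
# benchmarking run end-to-end with no external databases. Nucleotide sequence
# is generated only to satisfy format round-trips; detection consumes
# annotations, so codon-level realism is not attempted.

#' Load a synthetic-data preset
#'
#' Presets define one generator profile per viral group and per non-viral
#' source (prokaryote, eukaryote, plasmid). Three presets ship with the
#' package: `"easy"` (well-separated viral/host statistics), `"hard"`
#' (overlapping distributions), and `"provirus"` (one phage-like and one
#' host-like profile for integration tests). A file path to a user YAML with
#' the same schema is also accepted.
#'
#' @param name Preset name or path to a YAML file.
#' @return A validated preset list with elements `name`, `viral` (named list
#'   of profiles), `nonviral` (named list of profiles).
#' @export
load_preset <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "presets", paste0(name, ".yaml"),
                package = "viroscan")
  if (!nzchar(path) || !file.exists(path)) stop("unknown preset: ", name)
  p <- yaml::read_yaml(path)
  stopifnot(!is.null(p$viral), !is.null(p$nonviral))
  for (side in c("viral", "nonviral")) {
    for (nm in names(p[[side]])) {
      p[[side]][[nm]] <- validate_profile(p[[side]][[nm]], nm)
    }
  }
  p
}

validate_profile <- function(pr, name) {
  pr$name <- name
  check_probs <- function(v, what, levels) {
    if (!all(levels %in% names(v))) {
      stop("profile ", name, ": ", what, " must cover ",
           paste(levels, collapse = ","))
    }
    v <- unlist(v)[levels]
    if (abs(sum(v) - 1) > 1e-6) stop("profile ", name, ": ", what,
                                     " probabilities must sum to 1")
    if (any(v < 0)) stop("profile ", name, ": negative probability in ", what)
    v
  }
  pr$p_category <- check_probs(pr$p_category, "p_category", ALL_CATEGORIES)
  pr$start_codon <- check_probs(pr$start_codon, "start_codon",
                                c("ATG", "GTG", "TTG", "other"))
  pr$rbs <- check_probs(pr$rbs, "rbs", rbs_bins())
  for (f in c("gene_len", "gc", "bit_score")) {
    stopifnot(length(pr[[f]]) == 2, pr[[f]][2] >= 0)
  }
  stopifnot(pr$gene_density > 0, pr$p_hallmark >= 0, pr$p_hallmark <= 1,
            pr$p_strand_switch >= 0, pr$p_strand_switch <= 1,
            pr$p_overlap >= 0, pr$p_overlap <= 1)
  pr
}

#' Deterministic synthetic profile catalog for a set of viral groups
#'
#' One pool of generic profile ids per category plus, per group, a pool of
#' hallmark profiles (category viral, hallmark flag set to that group).
#'
#' @param groups Character vector of group names.
#' @param n_per_category Generic profiles per category.
#' @param n_hallmark Hallmark profiles per group.
#' @return Catalog data frame (`profile_id`, `category`, `hallmark_groups`).
#' @export
make_catalog <- function(groups, n_per_category = 30, n_hallmark = 8) {
  generic <- do.call(rbind, lapply(CATEGORIES, function(cc) {
    data.frame(profile_id = sprintf("%s_%03d", cc, seq_len(n_per_category)),
               category = cc, hallmark_groups = "",
               stringsAsFactors = FALSE)
  }))
  hm <- do.call(rbind, lapply(groups, function(g) {
    data.frame(profile_id = sprintf("hm_%s_%02d", g, seq_len(n_hallmark)),
               category = "viral", hallmark_groups = g,
               stringsAsFactors = FALSE)
  }))
  rbind(generic, hm)
}

# Truncated-normal sampler (lower truncation), exact via inverse CDF.
rtnorm_low <- function(n, mean, sd, low) {
  if (sd <= 0) return(pmax(rep(mean, n), low))
  u <- stats::runif(n, stats::pnorm(low, mean, sd), 1)
  stats::qnorm(pmin(u, 1 - 1e-12), mean, sd)
}

# Sample a DNA string of given length and GC fraction.
sample_seq <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

#' Simulate one annotated contig from a generator profile
#'
#' Genes are laid 5' to 3' with normally distributed lengths (truncated at 90
#' bp), intergenic gaps tuned to the profile's gene-density target, strand
#' flips with probability `p_strand_switch`, and same-strand overlaps with
#' probability `p_overlap`. Each gene draws a category from `p_category`;
#' non-unaligned genes emit one profile hit with a bit score truncated at 30,
#' and viral genes additionally carry a group hallmark profile with
#' probability `p_hallmark`. A small fraction of genes also emit a spurious
#' below-cutoff hit so that the bit-score filter is exercised.
#'
#' @param profile A generator profile from [load_preset()].
#' @param length_bp Contig length (>= 1000).
#' @param id Contig id.
#' @param seed Optional integer seed (`set.seed` is called when non-NULL).
#' @param with_seq Generate the nucleotide sequence (TRUE) or annotation only
#'   (FALSE; per-gene GC is then the sampled target value).
#' @param catalog Profile catalog ([make_catalog()]); defaults to a catalog
#'   for [default_groups()].
#' @return List with elements `ann` (a `contig_ann`), `hits` (hit data frame
#'   in the [read_hit_table()] schema, categories joined), and `catalog`.
#' @export
simulate_contig <- function(profile, length_bp, id = "contig_1", seed = NULL,
                            with_seq = TRUE, catalog = NULL) {
  if (length_bp < 1000) stop("length_bp must be >= 1000, got ", length_bp)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(catalog)) catalog <- make_catalog(default_groups())

  len_mean <- profile$gene_len[1]; len_sd <- profile$gene_len[2]
  period <- 1000 / profile$gene_density
  gap_mean <- max(1, period - len_mean)

  start <- integer(0); end <- integer(0); strand <- character(0)
  cur_strand <- sample(c("+", "-"), 1)
  prev_end <- 0L; prev_start <- 0L
  first_gap <- sample.int(max(1L, as.integer(round(gap_mean))), 1)
  repeat {
    len <- max(90L, as.integer(round(stats::rnorm(1, len_mean, len_sd))))
    if (length(start) == 0) {
      s <- first_gap
    } else {
      if (stats::runif(1) < profile$p_strand_switch) {
        cur_strand <- setdiff(c("+", "-"), cur_strand)
        same <- FALSE
      } else same <- TRUE
      if (same && stats::runif(1) < profile$p_overlap) {
        s <- max(prev_start + 1L, prev_end - sample.int(30L, 1) + 1L)
      } else {
        gap <- max(0L, as.integer(round(stats::rnorm(1, gap_mean, gap_mean / 2))))
        s <- prev_end + 1L + gap
      }
    }
    e <- s + len - 1L
    if (e > length_bp) {
      if (length(start) == 0 && s + 90L - 1L <= length_bp) {
        e <- as.integer(length_bp)   # clamp a lone oversized first gene
      } else break
    }
    start <- c(start, as.integer(s)); end <- c(end, as.integer(e))
    strand <- c(strand, cur_strand)
    prev_start <- as.integer(s); prev_end <- as.integer(e)
  }
  n <- length(start)
  if (n == 0) stop("infeasible density/length combination for profile ",
                   profile$name, " at ", length_bp, " bp")

  category <- sample(ALL_CATEGORIES, n, replace = TRUE, prob = profile$p_category)
  start_codon <- sample(c("ATG", "GTG", "TTG", "other"), n, replace = TRUE,
                        prob = profile$start_codon)
  rbs <- sample(rbs_bins(), n, replace = TRUE, prob = profile$rbs)
  gc_target <- pmin(0.8, pmax(0.2, stats::rnorm(n, profile$gc[1], profile$gc[2])))

  seq <- NULL
  gc <- gc_target
  if (with_seq) {
    bases <- sample(c("A", "C", "G", "T"), length_bp, replace = TRUE)
    for (i in seq_len(n)) {
      span <- start[i]:end[i]
      p <- c(A = (1 - gc_target[i]) / 2, C = gc_target[i] / 2,
             G = gc_target[i] / 2, T = (1 - gc_target[i]) / 2)
      bases[span] <- sample(names(p), length(span), replace = TRUE, prob = p)
    }
    seq <- paste(bases, collapse = "")
    gc <- gc_of_spans(seq, start, end)
  }

  # One retained hit per non-unaligned gene; hallmark profiles for a fraction
  # of viral genes when the profile belongs to a viral group.
  is_viral_group <- profile$name %in% catalog$hallmark_groups
  hallmark <- rep("", n)
  profile_id <- rep(NA_character_, n)
  bit <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (category[i] == "unaligned") next
    if (category[i] == "viral" && is_viral_group &&
        stats::runif(1) < profile$p_hallmark) {
      pool <- catalog$profile_id[catalog$hallmark_groups == profile$name]
      hallmark[i] <- profile$name
    } else {
      pool <- catalog$profile_id[catalog$category == category[i] &
                                   catalog$hallmark_groups == ""]
    }
    profile_id[i] <- sample(pool, 1)
    bit[i] <- rtnorm_low(1, profile$bit_score[1], profile$bit_score[2], 30)
  }
  has_hit <- !is.na(profile_id)
  hits <- data.frame(contig_id = rep(id, sum(has_hit)),
                     gene_index = (seq_len(n) - 1L)[has_hit],
                     profile_id = profile_id[has_hit],
                     bit_score = bit[has_hit],
                     stringsAsFactors = FALSE)
  # Spurious sub-cutoff hits: never change the best-hit assignment.
  spur <- which(stats::runif(n) < 0.05)
  if (length(spur)) {
    sc <- sample(CATEGORIES, length(spur), replace = TRUE)
    sp <- vapply(sc, function(cc)
      sample(catalog$profile_id[catalog$category == cc &
                                  catalog$hallmark_groups == ""], 1),
      character(1))
    hits <- rbind(hits, data.frame(
      contig_id = id, gene_index = spur - 1L, profile_id = sp,
      bit_score = stats::runif(length(spur), 10, 29.9),
      stringsAsFactors = FALSE))
  }
  idx <- match(hits$profile_id, catalog$profile_id)
  hits$category <- catalog$category[idx]
  hits$hallmark_groups <- catalog$hallmark_groups[idx]

  genes <- data.frame(index = seq_len(n) - 1L, start = start, end = end,
                      strand = strand, start_codon = start_codon, gc = gc,
                      rbs = rbs, category = category,
                      best_score = bit, hallmark = hallmark,
                      stringsAsFactors = FALSE)
  list(ann = new_contig_ann(id, length_bp, genes, seq = seq),
       hits = hits, catalog = catalog)
}

#' Simulate a provirus: host-viral-host concatenation with known boundaries
#'
#' A viral segment generated from `viral_profile` is inserted at a random
#' internal position of a host contig generated from `host_profile`. The
#' returned truth records the viral gene interval and base-pair span.
#'
#' @param host_profile,viral_profile Generator profiles.
#' @param host_len Total host length (>= 2000; split into two flanks of at
#'   least 1000 bp each).
#' @param viral_len Viral segment length (>= 1000).
#' @param id Contig id.
#' @param seed Optional integer seed.
#' @param with_seq Generate nucleotide sequence.
#' @param catalog Optional profile catalog.
#' @return List with `ann`, `hits`, `catalog` and `truth` (list with
#'   `first_gene`, `last_gene`, `start_bp`, `end_bp`).
#' @export
simulate_provirus <- function(host_profile, viral_profile, host_len, viral_len,
                              id = "provirus_1", seed = NULL, with_seq = TRUE,
                              catalog = NULL) {
  stopifnot(host_len >= 2000, viral_len >= 1000)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(catalog)) catalog <- make_catalog(default_groups())
  left_len <- sample(1000:(host_len - 1000), 1)
  right_len <- host_len - left_len
  parts <- list(
    simulate_contig(host_profile, left_len, id = id, with_seq = with_seq,
                    catalog = catalog),
    simulate_contig(viral_profile, viral_len, id = id, with_seq = with_seq,
                    catalog = catalog),
    simulate_contig(host_profile, right_len, id = id, with_seq = with_seq,
                    catalog = catalog)
  )
  offsets <- c(0L, left_len, left_len + viral_len)
  genes <- do.call(rbind, lapply(seq_along(parts), function(k) {
    g <- parts[[k]]$ann$genes
    g$start <- g$start + offsets[k]
    g$end <- g$end + offsets[k]
    g
  }))
  genes$index <- seq_len(nrow(genes)) - 1L
  rownames(genes) <- NULL
  n_per <- vapply(parts, function(p) nrow(p$ann$genes), integer(1))
  hits <- do.call(rbind, lapply(seq_along(parts), function(k) {
    h <- parts[[k]]$hits
    h$gene_index <- h$gene_index + sum(n_per[seq_len(k - 1)])
    h
  }))
  seq <- if (with_seq)
    paste(vapply(parts, function(p) p$ann$seq, character(1)), collapse = "")
  else NULL
  truth <- list(first_gene = n_per[1], last_gene = n_per[1] + n_per[2] - 1L,
                start_bp = left_len + 1L, end_bp = left_len + viral_len)
  list(ann = new_contig_ann(id, host_len + viral_len, genes, seq = seq),
       hits = hits, catalog = catalog, truth = truth)
}

#' Simulate labeled benchmark datasets of viral and non-viral fragments
#'
#' Per replicate and fragment length, `n_viral` fragments are drawn across
#' the requested viral groups and `n_nonviral` fragments across the three
#' non-viral sources (prokaryote, eukaryote, plasmid) in near-equal shares.
#'
#' @param groups Viral group names (must exist in the preset).
#' @param preset Preset list from [load_preset()] or a preset name.
#' @param n_viral,n_nonviral Fragments per class, default 50 each.
#' @param lengths Fragment lengths in bp, default
#'   `c(1500, 3000, 5000, 10000, 20000)`.
#' @param replicates Number of replicate datasets per length, default 5.
#' @param seed Optional integer seed.
#' @param with_seq Generate nucleotide sequences.
#' @return List of datasets, each a list with `length`, `replicate`, `anns`
#'   (named list of `contig_ann`), `hits` (combined hit table), `truth`
#'   (data frame: `contig_id`, `label` in viral/nonviral, `source`).
#' @export
simulate_benchmark <- function(groups, preset = "easy", n_viral = 50,
                               n_nonviral = 50,
                               lengths = c(1500, 3000, 5000, 10000, 20000),
                               replicates = 5, seed = NULL, with_seq = FALSE) {
  if (is.character(preset)) preset <- load_preset(preset)
  stopifnot(all(groups %in% names(preset$viral)))
  if (!is.null(seed)) set.seed(seed)
  catalog <- make_catalog(default_groups())
  out <- list()
  for (len in lengths) {
    for (rep_i in seq_len(replicates)) {
      v_src <- sample(rep_len(groups, n_viral))
      nv_src <- sample(rep_len(names(preset$nonviral), n_nonviral))
      src <- c(v_src, nv_src)
      label <- rep(c("viral", "nonviral"), c(n_viral, n_nonviral))
      anns <- vector("list", length(src))
      hits <- vector("list", length(src))
      ids <- sprintf("bench_%d_%d_%03d", len, rep_i, seq_along(src))
      for (i in seq_along(src)) {
        pr <- if (label[i] == "viral") preset$viral[[src[i]]] else
          preset$nonviral[[src[i]]]
        sim <- simulate_contig(pr, len, id = ids[i], with_seq = with_seq,
                               catalog = catalog)
        anns[[i]] <- sim$ann
        hits[[i]] <- sim$hits
      }
      names(anns) <- ids
      out[[length(out) + 1]] <- list(
        length = len, replicate = rep_i, anns = anns,
        hits = do.call(rbind, hits),
        truth = data.frame(contig_id = ids, label = label, source = src,
                           stringsAsFactors = FALSE))
    }
  }
  out
}

#' Simulate training genome collections for all groups and negative sources
#'
#' Genome lengths are drawn uniformly from each profile's `genome_len` range.
#'
#' @param preset Preset list or name.
#' @param groups Viral groups to simulate.
#' @param n_per_group Genomes per viral group.
#' @param n_negative Genomes per non-viral source.
#' @param seed Optional integer seed.
#' @param with_seq Generate nucleotide sequences (annotation-only is much
#'   faster and sufficient for training).
#' @return List with `viral` (named list of lists of `contig_ann`) and
#'   `negatives` (same for prokaryote/eukaryote/plasmid).
#' @export
simulate_training_genomes <- function(preset = "easy", groups = default_groups(),
                                      n_per_group = 30, n_negative = 30,
                                      seed = NULL, with_seq = FALSE) {
  if (is.character(preset)) preset <- load_preset(preset)
  stopifnot(all(groups %in% names(preset$viral)))
  if (!is.null(seed)) set.seed(seed)
  catalog <- make_catalog(default_groups())
  sim_set <- function(pr, n, tag) {
    lapply(seq_len(n), function(i) {
      len <- sample(pr$genome_len[1]:pr$genome_len[2], 1)
      simulate_contig(pr, len, id = sprintf("%s_g%03d", tag, i),
                      with_seq = with_seq, catalog = catalog)$ann
    })
  }
  viral <- lapply(groups, function(g) sim_set(preset$viral[[g]], n_per_group, g))
  names(viral) <- groups
  negatives <- lapply(names(preset$nonviral), function(s)
    sim_set(preset$nonviral[[s]], n_negative, s))
  names(negatives) <- names(preset$nonviral)
  list(viral = viral, negatives = negatives)
}

#' Write synthetic data as pipeline input files
#'
#' Emits the exact formats consumed by the input layer: a contig FASTA, a
#' GFF3 of CDS features with `start_codon`, `rbs_motif`, `gc_cont`
#' attributes, a tab-separated hit table, the profile catalog, and (when
#' truth is given) a truth TSV.
#'
#' @param anns Named list of `contig_ann` objects (with sequences).
#' @param hits Combined hit table.
#' @param catalog Profile catalog.
#' @param dir Output directory (created if needed).
#' @param truth Optional truth data frame written as `truth.tsv`.
#' @return Named list of written file paths.
#' @export
write_synthetic_inputs <- function(anns, hits, catalog, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- vapply(anns, function(a) {
    if (is.null(a$seq)) stop("contig ", a$id, " has no sequence; ",
                             "simulate with with_seq = TRUE")
    a$seq
  }, character(1))
  fa <- Biostrings::DNAStringSet(seqs)
  names(fa) <- vapply(anns, `[[`, character(1), "id")
  fasta_path <- file.path(dir, "contigs.fa")
  Biostrings::writeXStringSet(fa, fasta_path)

  gtabs <- lapply(anns, function(a) {
    g <- a$genes
    if (nrow(g) == 0) return(NULL)
    cbind(data.frame(contig_id = a$id, stringsAsFactors = FALSE), g)
  })
  gall <- do.call(rbind, gtabs[!vapply(gtabs, is.null, logical(1))])
  gff_path <- file.path(dir, "genes.gff3")
  gr_all <- GenomicRanges::GRanges(
    gall$contig_id, IRanges::IRanges(gall$start, gall$end),
    strand = gall$strand,
    seqlengths = structure(Biostrings::width(fa), names = names(fa)))
  S4Vectors::mcols(gr_all) <- S4Vectors::DataFrame(
    source = "viroscan_sim", type = "CDS", phase = 0L,
    ID = sprintf("%s_%d", gall$contig_id, gall$index + 1L),
    start_codon = gall$start_codon, rbs_motif = gall$rbs,
    gc_cont = sprintf("%.4f", gall$gc))
  rtracklayer::export(gr_all, gff_path, format = "gff3")

  hits_path <- file.path(dir, "hits.tsv")
  utils::write.table(hits[, c("contig_id", "gene_index", "profile_id",
                              "bit_score")],
                     hits_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat_path <- file.path(dir, "catalog.tsv")
  cat_out <- catalog
  cat_out$hallmark_groups[cat_out$hallmark_groups == ""] <- "-"
  utils::write.table(cat_out, cat_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- list(fasta = fasta_path, gff = gff_path, hits = hits_path,
                catalog = cat_path)
  if (!is.null(truth)) {
    truth_path <- file.path(dir, "truth.tsv")
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$truth <- truth_path
  }
  paths
}
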