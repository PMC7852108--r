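# Input layer: contigs (FASTA), gene calls (GFF3), profile-hit tables (TSV),
# and per-gene category assignment by best retained hit.

#' Read assembled contigs from a FASTA file
#'
#' Sequences are uppercased; characters outside `{A,C,G,T,N}` are mapped to
#' `N` with a warning. Duplicate ids and empty files are hard errors.
#'
#' @param path Path to a DNA FASTA file.
#' @return A [Biostrings::DNAStringSet] named by the first whitespace-delimited
#'   token of each header.
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate id ", dup[1], " in ", path)
  seqs <- toupper(as.character(ss))
  if (any(!nzchar(seqs))) stop("zero-length sequence in ", path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning(sum(bad), " sequence(s) contain non-ACGTN characters; mapped to N")
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

# Normalize a start-codon attribute to {ATG, GTG, TTG, other}.
norm_start_codon <- function(x) {
  x <- toupper(as.character(x))
  x[is.na(x) | !(x %in% c("ATG", "GTG", "TTG"))] <- "other"
  x
}

# GC fraction of [start, end] spans of a contig sequence (fallback when the
# gene table carries no gc attribute).
gc_of_spans <- function(seq, start, end) {
  vapply(seq_along(start), function(i) {
    s <- substr(seq, start[i], end[i])
    n <- nchar(s)
    if (n == 0) return(0)
    gc <- nchar(gsub("[^GCgc]", "", s))
    gc / n
  }, numeric(1))
}

#' Read per-contig gene calls from a GFF3 file
#'
#' CDS records are grouped per contig, sorted by start then end, and indexed
#' consecutively from 0. Recognized attributes: `start_codon` (missing maps
#' to `"other"`), `rbs_motif` (missing maps to bin `"None"`), `gc_cont`
#' (missing is computed from the contig sequence). Raw RBS motifs are binned
#' through [bin_rbs_motif()].
#'
#' @param path Path to a GFF3 file of CDS features.
#' @param contigs A [Biostrings::DNAStringSet] from [read_contigs()]; every
#'   gene's seqid must name one of its contigs and lie within its bounds.
#' @param rbs_map Optional RBS mapping table passed to [bin_rbs_motif()].
#' @return Named list (one entry per contig, in `contigs` order) of gene
#'   data frames with columns `index`, `start`, `end`, `strand`,
#'   `start_codon`, `gc`, `rbs`. Contigs without genes get a 0-row frame.
#' @export
read_genes <- function(path, contigs, rbs_map = NULL) {
  if (!file.exists(path)) stop("GFF file not found: ", path)
  gff <- as.data.frame(rtracklayer::readGFF(path))
  gff <- gff[as.character(gff$type) == "CDS", , drop = FALSE]
  gff$seqid <- as.character(gff$seqid)
  unknown <- setdiff(unique(gff$seqid), names(contigs))
  if (length(unknown)) {
    stop("gene on unknown contig: ", unknown[1])
  }
  lens <- Biostrings::width(contigs)
  names(lens) <- names(contigs)
  out_of_bounds <- gff$start < 1 | gff$end > lens[gff$seqid] | gff$start > gff$end
  if (any(out_of_bounds)) {
    i <- which(out_of_bounds)[1]
    stop("gene outside contig bounds: ", gff$seqid[i], ":",
         gff$start[i], "-", gff$end[i])
  }
  if (!"start_codon" %in% names(gff)) gff$start_codon <- NA_character_
  if (!"rbs_motif" %in% names(gff)) gff$rbs_motif <- NA_character_
  has_gc <- "gc_cont" %in% names(gff)

  out <- vector("list", length(contigs))
  names(out) <- names(contigs)
  for (id in names(contigs)) {
    g <- gff[gff$seqid == id, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    n <- nrow(g)
    gc <- if (has_gc) suppressWarnings(as.numeric(g$gc_cont)) else rep(NA_real_, n)
    if (anyNA(gc) && n > 0) {
      miss <- is.na(gc)
      gc[miss] <- gc_of_spans(as.character(contigs[[id]]),
                              g$start[miss], g$end[miss])
    }
    out[[id]] <- data.frame(
      index = seq_len(n) - 1L,
      start = as.integer(g$start),
      end = as.integer(g$end),
      strand = as.character(g$strand),
      start_codon = norm_start_codon(g$start_codon),
      gc = gc,
      rbs = bin_rbs_motif(g$rbs_motif, map = rbs_map),
      stringsAsFactors = FALSE
    )
  }
  out
}

#' Read a profile catalog mapping profile ids to categories and hallmark flags
#'
#' @param path TSV with header columns `profile_id`, `category`,
#'   `hallmark_groups` (comma-separated group names, or `-` for none).
#' @return Data frame with columns `profile_id`, `category`,
#'   `hallmark_groups` (empty string for none).
#' @export
read_profile_catalog <- function(path) {
  cat <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("profile_id", "category", "hallmark_groups")
  if (!all(need %in% names(cat))) {
    stop("profile catalog must have columns: ", paste(need, collapse = ", "))
  }
  bad <- !(cat$category %in% CATEGORIES)
  if (any(bad)) {
    stop("unknown category '", cat$category[which(bad)[1]], "' in catalog")
  }
  if (anyDuplicated(cat$profile_id)) {
    stop("duplicate profile_id in catalog: ",
         cat$profile_id[duplicated(cat$profile_id)][1])
  }
  cat$hallmark_groups[cat$hallmark_groups == "-"] <- ""
  hm_nonviral <- nzchar(cat$hallmark_groups) & cat$category != "viral"
  if (any(hm_nonviral)) {
    stop("hallmark flags on non-viral profile: ",
         cat$profile_id[which(hm_nonviral)[1]])
  }
  cat
}

#' Read a tabular profile-search hit table
#'
#' @param path TSV with header columns `contig_id`, `gene_index`,
#'   `profile_id`, `bit_score` (one row per hit; a gene may have many).
#' @param catalog Profile catalog from [read_profile_catalog()]; every
#'   `profile_id` must be present (hard error otherwise).
#' @return Data frame of hits with `category` and `hallmark_groups` joined in.
#' @export
read_hit_table <- function(path, catalog) {
  hits <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  need <- c("contig_id", "gene_index", "profile_id", "bit_score")
  if (!all(need %in% names(hits))) {
    stop("hit table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(hits) == 0) {
    return(data.frame(contig_id = character(), gene_index = integer(),
                      profile_id = character(), bit_score = numeric(),
                      category = character(), hallmark_groups = character(),
                      stringsAsFactors = FALSE))
  }
  score <- suppressWarnings(as.numeric(hits$bit_score))
  bad <- is.na(score) | !is.finite(score)
  if (any(bad)) {
    stop("malformed bit_score at hit table line ", which(bad)[1] + 1L)
  }
  gi <- suppressWarnings(as.integer(hits$gene_index))
  if (anyNA(gi)) {
    stop("malformed gene_index at hit table line ", which(is.na(gi))[1] + 1L)
  }
  idx <- match(hits$profile_id, catalog$profile_id)
  if (anyNA(idx)) {
    stop("profile_id absent from catalog: ",
         hits$profile_id[which(is.na(idx))[1]])
  }
  data.frame(contig_id = hits$contig_id, gene_index = gi,
             profile_id = hits$profile_id, bit_score = score,
             category = catalog$category[idx],
             hallmark_groups = catalog$hallmark_groups[idx],
             stringsAsFactors = FALSE)
}

# Construct a contig_ann object from components (no validation beyond basics).
new_contig_ann <- function(id, length, genes, seq = NULL) {
  stopifnot(is.character(id), length >= 1)
  structure(list(id = id, length = as.integer(length),
                 genes = genes, seq = seq),
            class = "contig_ann")
}

#' @export
print.contig_ann <- function(x, ...) {
  cat("<contig_ann> ", x$id, ": ", x$length, " bp, ",
      nrow(x$genes), " genes\n", sep = "")
  if (nrow(x$genes) > 0) {
    tab <- table(factor(x$genes$category, levels = ALL_CATEGORIES))
    cat("  categories:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Assign each gene its category from the best retained profile hit
#'
#' Hits with `bit_score` below `score_cutoff` are discarded (the cutoff is
#' inclusive: a hit scoring exactly the cutoff is retained). Among retained
#' hits the single best by bit score wins; ties are broken by category
#' priority viral > archaeal > bacterial > eukaryotic > mixed, then
#' lexicographic profile id. Genes with no retained hit are `unaligned`.
#'
#' @param contigs [Biostrings::DNAStringSet] of contigs.
#' @param genes Per-contig gene tables from [read_genes()].
#' @param hits Hit table from [read_hit_table()].
#' @param score_cutoff Bit-score cutoff, default 30.
#' @return Named list of `contig_ann` objects, one per contig, each holding
#'   the gene table extended with `category`, `best_score`, `hallmark`
#'   (comma-joined hallmark group names, `""` for none).
#' @export
annotate_contigs <- function(contigs, genes, hits, score_cutoff = 30) {
  hits <- hits[hits$bit_score >= score_cutoff, , drop = FALSE]
  best <- NULL
  if (nrow(hits) > 0) {
    prio <- match(hits$category, CATEGORIES)
    o <- order(hits$contig_id, hits$gene_index, -hits$bit_score,
               prio, hits$profile_id)
    hits <- hits[o, , drop = FALSE]
    keep <- !duplicated(paste(hits$contig_id, hits$gene_index, sep = "\r"))
    best <- hits[keep, , drop = FALSE]
  }
  out <- vector("list", length(contigs))
  names(out) <- names(contigs)
  for (id in names(contigs)) {
    g <- genes[[id]]
    if (is.null(g)) {
      g <- data.frame(index = integer(), start = integer(), end = integer(),
                      strand = character(), start_codon = character(),
                      gc = numeric(), rbs = character(),
                      stringsAsFactors = FALSE)
    }
    n <- nrow(g)
    g$category <- rep("unaligned", n)
    g$best_score <- rep(NA_real_, n)
    g$hallmark <- rep("", n)
    if (!is.null(best) && n > 0) {
      b <- best[best$contig_id == id, , drop = FALSE]
      m <- match(b$gene_index, g$index)
      if (anyNA(m)) stop("hit references unknown gene index on contig ", id)
      g$category[m] <- b$category
      g$best_score[m] <- b$bit_score
      g$hallmark[m] <- b$hallmark_groups
    }
    out[[id]] <- new_contig_ann(id, Biostrings::width(contigs)[match(id, names(contigs))],
                                g, seq = as.character(contigs[[id]]))
  }
  out
}

# Flatten a list of contig_ann gene tables into one data frame (cache format).
flatten_annotation <- function(anns) {
  rows <- lapply(anns, function(a) {
    g <- a$genes
    if (nrow(g) == 0) return(NULL)
    cbind(data.frame(contig_id = a$id, stringsAsFactors = FALSE), g)
  })
  lens <- data.frame(contig_id = vapply(anns, `[[`, character(1), "id"),
                     length = vapply(anns, `[[`, integer(1), "length"),
                     stringsAsFactors = FALSE)
  list(genes = do.call(rbind, rows), contigs = lens)
}

# Rebuild contig_ann objects from flatten_annotation() tables (+ optional seqs).
unflatten_annotation <- function(flat, contigs = NULL) {
  out <- vector("list", nrow(flat$contigs))
  names(out) <- flat$contigs$contig_id
  for (i in seq_len(nrow(flat$contigs))) {
    id <- flat$contigs$contig_id[i]
    g <- if (is.null(flat$genes)) NULL else
      flat$genes[flat$genes$contig_id == id, , drop = FALSE]
    if (is.null(g) || nrow(g) == 0) {
      g <- data.frame(index = integer(), start = integer(), end = integer(),
                      strand = character(), start_codon = character(),
                      gc = numeric(), rbs = character(), category = character(),
                      best_score = numeric(), hallmark = character(),
                      stringsAsFactors = FALSE)
    } else {
      g$contig_id <- NULL
      g <- g[order(g$start, g$end), , drop = FALSE]
      rownames(g) <- NULL
      g$hallmark[is.na(g$hallmark)] <- ""
    }
    seq <- if (!is.null(contigs) && id %in% names(contigs)) {
      as.character(contigs[[id]])
    } else NULL
    out[[i]] <- new_contig_ann(id, flat$contigs$length[i], g, seq = seq)
  }
  out
}
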