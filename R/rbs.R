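# Ribosome-binding-site motif binning.
#
# Gene callers report a free-text RBS motif per gene (e.g. prodigal's
# rbs_motif attribute). Classifiers consume an 11-bin summary of these
# motifs: Shine-Dalgarno variants, A/T-rich patterns, a catch-all "Other",
# and "None" for genes with no motif found.

#' The 11 RBS motif bins
#'
#' Fixed bin set used for the RBS composition features. The last bin,
#' `"None"`, collects genes for which no motif was reported.
#'
#' @return Character vector of length 11, in feature order.
#' @export
rbs_bins <- function() {
  c("SD_Canonical", "SD_Bacteroidetes", "TATATA_3-6", "OnlyA", "OnlyT",
    "DoubleA", "DoubleT", "Other_GA", "NoA", "Other", "None")
}

# Default raw-motif -> bin table. Shipped as editable TSV so users can
# substitute the exact mapping of their gene caller; these defaults cover the
# common prodigal motif strings heuristically.
default_rbs_map <- function() {
  if (is.null(.vs_env$rbs_map)) {
    path <- system.file("extdata", "rbs_map.tsv", package = "viroscan")
    .vs_env$rbs_map <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .vs_env$rbs_map
}

#' Bin a raw RBS motif string into one of the 11 motif bins
#'
#' Absent, empty or `"None"` motifs map to `"None"`; strings already equal to
#' a bin name map to themselves; other strings are looked up in a mapping
#' table (default shipped with the package, overridable); unmapped nonempty
#' strings fall back to `"Other"`.
#'
#' @param motif Character vector of raw motif strings (NA allowed).
#' @param map Optional data frame with columns `motif` and `bin` overriding
#'   the default mapping table.
#' @return Character vector of bin names, same length as `motif`.
#' @export
#' @examples
#' bin_rbs_motif(c(NA, "AGGAGG", "TATATA", "XYZ"))
bin_rbs_motif <- function(motif, map = NULL) {
  if (is.null(map)) map <- default_rbs_map()
  stopifnot(all(c("motif", "bin") %in% names(map)),
            all(map$bin %in% rbs_bins()))
  motif <- as.character(motif)
  out <- rep("Other", length(motif))
  none <- is.na(motif) | motif == "" | motif == "None"
  out[none] <- "None"
  is_bin <- !none & motif %in% rbs_bins()
  out[is_bin] <- motif[is_bin]
  idx <- match(motif, map$motif)
  hit <- !none & !is_bin & !is.na(idx)
  out[hit] <- map$bin[idx[hit]]
  out
}
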