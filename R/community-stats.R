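#' Abundance-weighted gene-length statistics
#'
#' Mean and standard deviation of ORF length weighted by TPM abundance:
#' `mean = sum(len * w) / sum(w)` and
#' `sd = sqrt(sum(w * (len - mean)^2) / sum(w))` (frequency-weight
#' variance, no Bessel correction, consistent with the weighted-mean
#' estimand). By default only complete CDSs (both start and stop codon
#' present) enter the statistic, which avoids truncation bias from contig
#' edges.
#'
#' @param table ORF table tibble.
#' @param sample One sample id to weight by, or `"pooled"` (default) to sum
#'   TPM across samples, matching a co-assembled metagenome where each ORF
#'   is one row shared by all samples.
#' @param require_complete Drop ORFs missing a start or stop codon.
#' @return One-row tibble: `mean_bp`, `sd_bp`, `n_used`, `n_excluded`.
#' @examples
#' # lengths 300/900 at weights 100/300: mean 750, sd sqrt(67500)
#' @export
weighted_gene_length <- function(table, sample = "pooled", require_complete = TRUE) {
  if (nrow(table) == 0) stop_deut("statistic", "empty table")
  w <- gene_weights(table, sample)
  keep <- if (require_complete) table$has_start & table$has_stop else rep(TRUE, nrow(table))
  n_excluded <- sum(!keep)
  len <- table$length_bp[keep]
  w <- w[keep]
  if (sum(w) <= 0) stop_deut("statistic", "total weight is zero after filtering")
  m <- sum(len * w) / sum(w)
  v <- sum(w * (len - m)^2) / sum(w)
  tibble::tibble(mean_bp = m, sd_bp = sqrt(v),
                 n_used = sum(keep), n_excluded = n_excluded)
}

gene_weights <- function(table, sample) {
  if (identical(sample, "pooled")) {
    cols <- tpm_cols(table)
    rowSums(as.matrix(table[cols]))
  } else {
    col <- paste0("tpm_", sample)
    if (!col %in% names(table)) stop_deut("key", sprintf("unknown sample '%s'", sample))
    table[[col]]
  }
}

#' G+C content
#'
#' For a nucleotide string, the fraction of G/C bases. For an ORF table,
#' the mean of per-record `gc_fraction`, optionally TPM-weighted.
#'
#' @param x Nucleotide string or ORF table tibble.
#' @param weights For tables: `NULL` (unweighted), `"pooled"`, or a sample
#'   id, selecting TPM weights as in [weighted_gene_length()].
#' @return G+C fraction in \[0, 1\].
#' @export
gc_content <- function(x, weights = NULL) {
  if (is.character(x) && length(x) == 1) {
    if (!nzchar(x)) stop_deut("statistic", "empty sequence")
    bases <- strsplit(toupper(x), "")[[1]]
    return(mean(bases %in% c("G", "C")))
  }
  if (nrow(x) == 0) stop_deut("statistic", "empty table")
  if (is.null(weights)) return(mean(x$gc_fraction))
  w <- gene_weights(x, weights)
  if (sum(w) <= 0) stop_deut("statistic", "total weight is zero")
  sum(x$gc_fraction * w) / sum(w)
}

#' Species richness of one sample
#'
#' Counts distinct species tags (last field of the lineage) with TPM > 0 in
#' the given sample. `unknown_<k>` tags — species-level placeholders for
#' unclassified lineages — are excluded unless `include_unknowns`.
#'
#' @param table ORF table tibble.
#' @param sample Sample id.
#' @param include_unknowns Count `unknown_<k>` species tags too.
#' @return Integer richness.
#' @export
species_richness <- function(table, sample, include_unknowns = FALSE) {
  col <- paste0("tpm_", sample)
  if (!col %in% names(table)) stop_deut("key", sprintf("unknown sample '%s'", sample))
  tags <- unique(species_tag(table$taxon[table[[col]] > 0]))
  if (!include_unknowns) tags <- tags[!is_unknown_tag(tags)]
  length(tags)
}

#' Species presence set of one sample
#'
#' @inheritParams species_richness
#' @return Character vector of species tags with TPM > 0.
#' @export
species_set <- function(table, sample, include_unknowns = FALSE) {
  col <- paste0("tpm_", sample)
  if (!col %in% names(table)) stop_deut("key", sprintf("unknown sample '%s'", sample))
  tags <- unique(species_tag(table$taxon[table[[col]] > 0]))
  if (!include_unknowns) tags <- tags[!is_unknown_tag(tags)]
  tags
}

#' Jaccard similarity between two presence sets
#'
#' `|A intersect B| / |A union B|` on presence/absence; a beta-diversity
#' proxy when no abundance or spatial-overlap information is available.
#'
#' @param set_a,set_b Character vectors of species tags.
#' @return Jaccard index in \[0, 1\].
#' @export
jaccard <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) == 0 && length(b) == 0) {
    stop_deut("statistic", "Jaccard undefined for two empty sets")
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' All pairwise Jaccard indices across samples of a table
#'
#' @param table ORF table tibble.
#' @param include_unknowns Passed to [species_set()].
#' @return Tibble: `sample_a`, `sample_b`, `jaccard`.
#' @export
jaccard_matrix <- function(table, include_unknowns = FALSE) {
  samples <- orf_samples(table)
  sets <- lapply(samples, species_set, table = table,
                 include_unknowns = include_unknowns)
  pairs <- utils::combn(seq_along(samples), 2)
  tibble::tibble(
    sample_a = samples[pairs[1, ]],
    sample_b = samples[pairs[2, ]],
    jaccard = apply(pairs, 2, function(ij) jaccard(sets[[ij[1]]], sets[[ij[2]]]))
  )
}
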