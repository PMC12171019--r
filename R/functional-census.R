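#' Matcher rule for annotation censuses
#'
#' An ORF matches if its gene name contains any keyword (case-insensitive
#' substring) OR its annotations intersect the orthogroup set. The default
#' is a conservative transposase rule: the literal keyword "transposase"
#' or membership in the putative IS3-family orthogroups COG2801/COG2963 —
#' no fuzzy matching.
#'
#' @param keywords Character vector of gene-name keywords.
#' @param orthogroups Character vector of KEGG/COG/Pfam identifiers.
#' @param description Free-text label recorded in results.
#' @return A `census_matcher` list.
#' @export
census_matcher <- function(keywords = "transposase",
                           orthogroups = c("COG2801", "COG2963"),
                           description = "transposase keyword or IS3-family COG") {
  if (length(keywords) == 0 && length(orthogroups) == 0) {
    stop_deut("config", "matcher needs at least one keyword or orthogroup")
  }
  structure(list(keywords = keywords, orthogroups = orthogroups,
                 description = description), class = "census_matcher")
}

matcher_hits <- function(table, matcher) {
  hit <- rep(FALSE, nrow(table))
  for (kw in matcher$keywords) {
    hit <- hit | stringr::str_detect(tolower(table$gene_name), stringr::fixed(tolower(kw)))
  }
  if (length(matcher$orthogroups)) {
    ann <- annotation_sets(table)
    hit <- hit | vapply(ann, function(a) any(a %in% matcher$orthogroups), TRUE)
  }
  hit
}

#' Census of a gene category across samples
#'
#' Per sample, the category's share of gene counts
#' (`100 * matching ORFs with TPM > 0 / ORFs with TPM > 0`) and its summed
#' TPM. Cross-sample mean and sd are unweighted sample statistics (sd with
#' n-1), as appropriate for a handful of replicate containers.
#'
#' @param table ORF table tibble.
#' @param matcher A [census_matcher()]; default is the conservative
#'   transposase rule.
#' @param denominator `"present"` (default) counts all ORFs with TPM > 0 in
#'   the sample; `"annotated"` restricts the denominator to ORFs carrying at
#'   least one annotation.
#' @return A `census_result` list: `per_sample` tibble (`sample`,
#'   `count_pct`, `tpm`), `mean_count_pct`, `sd_count_pct`, `mean_tpm`,
#'   `sd_tpm`, `matcher_description`.
#' @export
transposase_census <- function(table, matcher = census_matcher(),
                               denominator = c("present", "annotated")) {
  denominator <- match.arg(denominator)
  if (nrow(table) == 0) stop_deut("statistic", "empty table")
  if (!inherits(matcher, "census_matcher")) {
    stop_deut("config", "`matcher` must be a census_matcher")
  }
  hit <- matcher_hits(table, matcher)
  annotated <- has_any_annotation(table) | nzchar(trimws(table$gene_name))
  samples <- orf_samples(table)
  rows <- lapply(samples, function(s) {
    tpm <- table[[paste0("tpm_", s)]]
    present <- tpm > 0
    denom <- if (denominator == "present") present else present & annotated
    tibble::tibble(sample = s,
                   count_pct = 100 * sum(hit & present) / sum(denom),
                   tpm = sum(tpm[hit]))
  })
  per_sample <- dplyr::bind_rows(rows)
  out <- list(per_sample = per_sample,
              mean_count_pct = mean(per_sample$count_pct),
              sd_count_pct = sd(per_sample$count_pct),
              mean_tpm = mean(per_sample$tpm),
              sd_tpm = sd(per_sample$tpm),
              matcher_description = matcher$description)
  class(out) <- "census_result"
  out
}

#' @export
print.census_result <- function(x, ...) {
  cat("Census:", x$matcher_description, "\n")
  cat(sprintf("  count %%: %.2f +/- %.2f\n", x$mean_count_pct, x$sd_count_pct))
  cat(sprintf("  TPM:     %.2f +/- %.2f\n", x$mean_tpm, x$sd_tpm))
  print(x$per_sample)
  invisible(x)
}

#' Per-gene summed TPM matrix
#'
#' One row per requested gene (or alias group written `"ada/alkA"`, whose
#' member names are pooled), one column per sample, each cell the sum of
#' TPM over ORFs whose gene name matches a member case-insensitively and
#' exactly. Genes absent from a sample give 0.
#'
#' @param table ORF table tibble.
#' @param gene_names Character vector of gene names / alias groups.
#' @return Tibble: `gene`, then one numeric column per sample.
#' @export
gene_tpm_table <- function(table, gene_names) {
  if (length(gene_names) == 0) stop_deut("config", "gene list is empty")
  samples <- orf_samples(table)
  gname <- tolower(trimws(table$gene_name))
  rows <- lapply(gene_names, function(g) {
    members <- tolower(trimws(strsplit(g, "/", fixed = TRUE)[[1]]))
    sel <- gname %in% members
    out <- tibble::tibble(gene = g)
    for (s in samples) out[[s]] <- sum(table[[paste0("tpm_", s)]][sel])
    out
  })
  dplyr::bind_rows(rows)
}

#' Fraction of orphan ORFs
#'
#' Orphans are predicted ORFs with no known homologue: empty annotation
#' cells (KEGG, COG, Pfam) and no gene name.
#'
#' @param table ORF table tibble.
#' @return Percentage of orphan ORFs (0-100).
#' @export
orphan_fraction <- function(table) {
  if (nrow(table) == 0) stop_deut("statistic", "empty table")
  orphan <- !has_any_annotation(table) & !nzchar(trimws(table$gene_name))
  100 * mean(orphan)
}
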