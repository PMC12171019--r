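#' Relative amino-acid composition matrix of a protein set
#'
#' One row per sequence with the relative frequencies of the 20 standard
#' amino acids; non-standard symbols (X, B, Z, U, O, gaps, stops) are
#' dropped before normalization, so every row sums to 1.
#'
#' @param sequences Tibble with columns `id` and `seq` (as returned by
#'   [read_fasta()]), or a named character vector of sequences.
#' @param group_label Label attached to the matrix for downstream tests.
#' @return An `aa_composition` tibble: `sequence_id`, then columns `A`
#'   through `Y` in alphabetical residue order; `attr(, "group_label")`.
#' @export
composition_matrix <- function(sequences, group_label = "group") {
  if (is.character(sequences)) {
    sequences <- tibble::tibble(
      id = if (is.null(names(sequences))) sprintf("seq_%03d", seq_along(sequences))
           else names(sequences),
      seq = unname(sequences))
  }
  if (nrow(sequences) == 0) stop_deut("value", "no sequences")
  rows <- matrix(0, nrow(sequences), 20, dimnames = list(NULL, AA20))
  for (i in seq_len(nrow(sequences))) {
    aa <- strsplit(toupper(sequences$seq[i]), "")[[1]]
    aa <- aa[aa %in% AA20]
    if (length(aa) == 0) {
      stop_deut("value", sprintf("sequence '%s' has no standard residues",
                                 sequences$id[i]))
    }
    tab <- table(factor(aa, levels = AA20))
    rows[i, ] <- as.numeric(tab) / length(aa)
  }
  out <- tibble::as_tibble(rows)
  out <- tibble::add_column(out, sequence_id = sequences$id, .before = 1)
  attr(out, "group_label") <- group_label
  class(out) <- c("aa_composition", class(out))
  out
}

aa_matrix <- function(m) {
  x <- as.matrix(m[AA20])
  storage.mode(x) <- "double"
  x
}

#' Mean pairwise self-correlation of a composition matrix
#'
#' Mean Pearson correlation over all unordered pairs of rows; a cohesion
#' measure for a protein family's residue usage. Pairs involving a
#' constant (zero-variance) row are skipped with a warning.
#'
#' @param matrix An `aa_composition` tibble (>= 2 rows).
#' @return Mean pairwise correlation in \[-1, 1\].
#' @export
group_self_correlation <- function(matrix) {
  x <- aa_matrix(matrix)
  if (nrow(x) < 2) stop_deut("statistic", "need at least two rows")
  constant <- apply(x, 1, function(r) stats::var(r) == 0)
  if (any(constant)) {
    rlang::warn(sprintf("%d constant row(s) skipped in self-correlation",
                        sum(constant)))
    x <- x[!constant, , drop = FALSE]
  }
  if (nrow(x) < 2) stop_deut("statistic", "fewer than two non-constant rows")
  cm <- stats::cor(t(x))
  mean(cm[upper.tri(cm)])
}

# Vectorized Welch / Student two-sample t-test over columns.
col_t_test <- function(xa, xb, var_equal = FALSE) {
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- apply(xa, 2, stats::var); vb <- apply(xb, 2, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(ma))
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / sqrt(se2)
  p <- 2 * pt(-abs(t), df)
  # Degenerate columns: zero variance in both groups.
  degen <- se2 == 0
  if (any(degen)) {
    t[degen] <- ifelse(ma[degen] == mb[degen], 0, sign(ma - mb)[degen] * Inf)
    p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
  }
  list(mean_a = ma, mean_b = mb, t = t, df = df, p = p)
}

#' Two-group per-residue enrichment test
#'
#' Unpaired two-sample t-tests (Welch by default) on each residue's
#' relative-frequency column, classifying each of the 20 residues as
#' `enriched` (higher in group A, significant), `depleted`, or `same`.
#' The compositional dependence among columns is acknowledged and ignored.
#'
#' @param a,b `aa_composition` tibbles with >= 2 rows each.
#' @param alpha Significance level (default 0.05).
#' @param correction `"none"` (default, raw per-test alpha) or `"bh"`
#'   (Benjamini-Hochberg, recommended when controlling the FDR across the
#'   20 tests matters).
#' @param var_equal Use Student's pooled-variance test instead of Welch.
#' @return An `aa_enrichment` tibble, one row per residue: `residue`,
#'   `mean_a`, `mean_b`, `t_statistic`, `p_value`, `adjusted_p`, `class`;
#'   classification counts in `attr(, "counts")`.
#' @export
enrichment_test <- function(a, b, alpha = 0.05,
                            correction = c("none", "bh"), var_equal = FALSE) {
  correction <- match.arg(correction)
  xa <- aa_matrix(a); xb <- aa_matrix(b)
  if (nrow(xa) < 2 || nrow(xb) < 2) stop_deut("statistic", "each group needs >= 2 rows")
  tt <- col_t_test(xa, xb, var_equal = var_equal)
  padj <- if (correction == "bh") stats::p.adjust(tt$p, "BH") else tt$p
  class_ <- ifelse(padj < alpha & tt$mean_a > tt$mean_b, "enriched",
                   ifelse(padj < alpha & tt$mean_a < tt$mean_b, "depleted", "same"))
  out <- tibble::tibble(residue = AA20, mean_a = unname(tt$mean_a),
                        mean_b = unname(tt$mean_b),
                        t_statistic = unname(tt$t), p_value = unname(tt$p),
                        adjusted_p = unname(padj), class = class_)
  counts <- c(n_enriched = sum(class_ == "enriched"),
              n_depleted = sum(class_ == "depleted"),
              n_same = sum(class_ == "same"))
  attr(out, "counts") <- counts
  attr(out, "alpha") <- alpha
  attr(out, "correction") <- correction
  class(out) <- c("aa_enrichment", class(out))
  out
}
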