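#' Per-taxon abundance/richness points from an ORF table
#'
#' Groups ORFs by species tag: `d_obs` is the number of distinct ORF ids
#' in the group (each ORF row is one unique sequence variant of the
#' co-assembly, shared across samples) and `A` the sum of their TPM over
#' the in-scope samples.
#'
#' @param table ORF table tibble.
#' @param environment_label Label carried into the points (e.g. a
#'   container or water-mass name).
#' @param gene_scope Optional character vector of annotation identifiers
#'   or gene names; ORFs are kept if their gene name or any annotation is
#'   in the scope (e.g. a nitrogen-gene subset).
#' @param samples Sample ids to sum abundance over (default: all).
#' @return Tibble: `taxon` (species tag), `environment`, `A`, `d_obs`.
#'   Empty after scoping gives a zero-row tibble with a warning.
#' @export
build_points <- function(table, environment_label = "env", gene_scope = NULL,
                         samples = NULL) {
  if (nrow(table) == 0) stop_deut("statistic", "empty table")
  if (is.null(samples)) samples <- orf_samples(table)
  cols <- paste0("tpm_", samples)
  missing <- setdiff(cols, names(table))
  if (length(missing)) stop_deut("key", sprintf("unknown sample(s): %s",
                                                paste(missing, collapse = ", ")))
  keep <- rep(TRUE, nrow(table))
  if (!is.null(gene_scope)) {
    ann <- annotation_sets(table)
    keep <- tolower(table$gene_name) %in% tolower(gene_scope) |
      vapply(ann, function(a) any(a %in% gene_scope), TRUE)
  }
  sub <- table[keep, , drop = FALSE]
  if (nrow(sub) == 0) {
    rlang::warn("no ORFs left after gene scoping")
    return(tibble::tibble(taxon = character(), environment = character(),
                          A = numeric(), d_obs = integer()))
  }
  sub$`.species` <- species_tag(sub$taxon)
  sub$`.A` <- rowSums(as.matrix(sub[cols]))
  sub |>
    dplyr::group_by(.data$.species) |>
    dplyr::summarise(A = sum(.data$.A), d_obs = dplyr::n_distinct(.data$orf_id),
                     .groups = "drop") |>
    dplyr::transmute(taxon = .data$.species, environment = environment_label,
                     A = .data$A, d_obs = as.integer(.data$d_obs))
}

#' Fit the abundance-richness power law
#'
#' Ordinary least squares of `log10(d_obs)` on `log10(A)`, i.e. the model
#' `d_exp = c * A^gamma`. `gamma` (the slope) measures how fast unique
#' sequence variants accrue with abundance; `c` is the variant count at
#' A = 1. Points with `d_obs < min_dobs` or `A <= 0` are excluded (log
#' undefined at zero richness) and counted.
#'
#' @param points Tibble with columns `A` and `d_obs` (see
#'   [build_points()] or [generate_richness_points()]).
#' @param min_dobs Minimum observed richness for inclusion (default 1).
#' @return A `power_law_fit` list: `c`, `gamma`, `se_c_log`, `se_gamma`,
#'   `r_squared`, `n_points`, `n_excluded`, `residuals` (per-point tibble
#'   with `log10(d_obs) - log10(d_exp)`), and the underlying `lm`.
#' @examples
#' fit_power_law(tibble::tibble(A = c(10, 100, 1000), d_obs = c(2, 20, 200)))
#' @export
fit_power_law <- function(points, min_dobs = 1) {
  use <- points$d_obs >= min_dobs & points$A > 0
  n_excluded <- sum(!use)
  pts <- points[use, , drop = FALSE]
  if (nrow(pts) < 3) stop_deut("fit", "need at least 3 usable points")
  lx <- log10(pts$A)
  ly <- log10(pts$d_obs)
  if (stats::var(lx) == 0) stop_deut("fit", "zero variance in log10(A)")
  model <- lm(ly ~ lx)
  sm <- summary(model)
  fit <- list(
    c = 10^unname(coef(model)[1]),
    gamma = unname(coef(model)[2]),
    se_c_log = unname(sm$coefficients[1, 2]),
    se_gamma = unname(sm$coefficients[2, 2]),
    r_squared = sm$r.squared,
    n_points = nrow(pts),
    n_excluded = n_excluded,
    residuals = tibble::tibble(
      taxon = if ("taxon" %in% names(pts)) pts$taxon else NA_character_,
      A = pts$A, d_obs = pts$d_obs,
      residual = unname(stats::residuals(model))),
    model = model
  )
  class(fit) <- "power_law_fit"
  fit
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law richness fit: d = %.4g * A^%.4f\n", x$c, x$gamma))
  cat(sprintf("  gamma = %.4f +/- %.4f, r^2 = %.3f, n = %d (excluded %d)\n",
              x$gamma, x$se_gamma, x$r_squared, x$n_points, x$n_excluded))
  invisible(x)
}

#' Expected richness under a fitted power law
#'
#' @param fit A `power_law_fit`.
#' @param A Abundance values.
#' @return `c * A^gamma`.
#' @export
expected_richness <- function(fit, A) fit$c * A^fit$gamma

#' Distribution of richness deviations (delta coefficients)
#'
#' `delta_i = d_obs_i / d_exp_i` with `d_exp = c * A^gamma` from the fit.
#' On the log10 axis zero means richness exactly as expected; the spread
#' (sd of log10 delta) measures how much taxa over- or under-diversify
#' relative to abundance. A Gaussian kernel density estimate of log10
#' delta is evaluated on a grid spanning the observed range plus three
#' bandwidths. Points with `d_obs = 0` are excluded (log undefined) and
#' counted. When deltas are computed against a fit of the same points, the
#' geometric mean of delta is 1 (OLS residuals average zero in log space).
#'
#' @param points Tibble with `A` and `d_obs`.
#' @param fit A `power_law_fit` for these points' environment.
#' @param kde_bandwidth Bandwidth: `"scott"` (default, [stats::bw.nrd()])
#'   or a positive number.
#' @return A `delta_distribution` list: `deltas` tibble (`taxon`, `A`,
#'   `d_obs`, `d_exp`, `delta`, `log_delta`), `kde` tibble (`x`,
#'   `density`), `spread`, `bandwidth`, `n_excluded`.
#' @export
delta_distribution <- function(points, fit, kde_bandwidth = "scott") {
  use <- points$d_obs > 0 & points$A > 0
  pts <- points[use, , drop = FALSE]
  if (nrow(pts) < 2) stop_deut("statistic", "need at least 2 positive-richness points")
  d_exp <- expected_richness(fit, pts$A)
  delta <- pts$d_obs / d_exp
  log_delta <- log10(delta)
  bw <- if (identical(kde_bandwidth, "scott")) bw.nrd(log_delta) else {
    if (!is.numeric(kde_bandwidth) || kde_bandwidth <= 0) {
      stop_deut("config", "kde_bandwidth must be 'scott' or a positive number")
    }
    kde_bandwidth
  }
  dens <- density(log_delta, bw = bw,
                  from = min(log_delta) - 3 * bw, to = max(log_delta) + 3 * bw)
  out <- list(
    deltas = tibble::tibble(
      taxon = if ("taxon" %in% names(pts)) pts$taxon else NA_character_,
      A = pts$A, d_obs = pts$d_obs, d_exp = d_exp,
      delta = delta, log_delta = log_delta),
    kde = tibble::tibble(x = dens$x, density = dens$y),
    spread = sd(log_delta),
    bandwidth = bw,
    n_excluded = sum(!use)
  )
  class(out) <- "delta_distribution"
  out
}

#' @export
print.delta_distribution <- function(x, ...) {
  cat(sprintf("delta distribution: %d taxa, spread (sd log10 delta) = %.4f\n",
              nrow(x$deltas), x$spread))
  invisible(x)
}

slope_se <- function(x) {
  if (inherits(x, "power_law_fit")) c(x$gamma, x$se_gamma)
  else if (is.list(x) && all(c("gamma", "se_gamma") %in% names(x))) {
    c(x$gamma, x$se_gamma)
  } else stop_deut("comparison", "expected a power_law_fit or list(gamma, se_gamma)")
}

#' Two-sample z comparison of power-law slopes
#'
#' `z = (gamma_a - gamma_b) / sqrt(se_a^2 + se_b^2)` with a two-sided
#' standard-normal p-value. Accepts fitted objects or bare
#' `list(gamma =, se_gamma =)` pairs, so slopes reported with standard
#' errors can be compared directly.
#'
#' @param fit_a,fit_b `power_law_fit` objects or `list(gamma, se_gamma)`.
#' @return One-row tibble: `z`, `p_value`.
#' @export
compare_slopes <- function(fit_a, fit_b) {
  a <- slope_se(fit_a); b <- slope_se(fit_b)
  joint <- sqrt(a[2]^2 + b[2]^2)
  if (!is.finite(joint) || joint <= 0) stop_deut("comparison", "zero joint standard error")
  z <- (a[1] - b[1]) / joint
  tibble::tibble(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Ratio of deviation-distribution spreads
#'
#' @param dist_a,dist_b `delta_distribution` objects.
#' @return `spread_a / spread_b` where spread is the sd of log10 delta.
#' @export
compare_spread <- function(dist_a, dist_b) {
  if (dist_b$spread <= 0) stop_deut("comparison", "zero spread in reference distribution")
  dist_a$spread / dist_b$spread
}
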