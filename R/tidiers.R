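#' Tidy a power-law richness fit
#'
#' @param x A `power_law_fit`.
#' @param ... Unused.
#' @return Tibble with one row per model quantity (`c`, `gamma`), columns
#'   `term`, `estimate`, `std_error` (on the scale the model is fitted:
#'   the intercept's error is on log10 c).
#' @method tidy power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(term = c("c", "gamma"),
                 estimate = c(x$c, x$gamma),
                 std_error = c(x$se_c_log, x$se_gamma))
}

#' @rdname tidy.power_law_fit
#' @method glance power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_points = x$n_points,
                 n_excluded = x$n_excluded)
}

#' Tidy a census result
#'
#' @param x A `census_result`.
#' @param ... Unused.
#' @return The per-sample tibble.
#' @method tidy census_result
#' @export
tidy.census_result <- function(x, ...) x$per_sample

#' @rdname tidy.census_result
#' @method glance census_result
#' @export
glance.census_result <- function(x, ...) {
  tibble::tibble(mean_count_pct = x$mean_count_pct,
                 sd_count_pct = x$sd_count_pct,
                 mean_tpm = x$mean_tpm, sd_tpm = x$sd_tpm,
                 matcher = x$matcher_description)
}

#' Tidy an enrichment result
#'
#' @param x An `aa_enrichment` tibble.
#' @param ... Unused.
#' @return The per-residue tibble (already tidy).
#' @method tidy aa_enrichment
#' @export
tidy.aa_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "aa_enrichment")
  out
}

#' @rdname tidy.aa_enrichment
#' @method glance aa_enrichment
#' @export
glance.aa_enrichment <- function(x, ...) {
  cnt <- attr(x, "counts")
  tibble::tibble(n_enriched = unname(cnt["n_enriched"]),
                 n_depleted = unname(cnt["n_depleted"]),
                 n_same = unname(cnt["n_same"]),
                 alpha = attr(x, "alpha"),
                 correction = attr(x, "correction"))
}

#' Tidy a batch ka/ks screen
#'
#' @param x A `kaks_screen` tibble.
#' @param ... Unused.
#' @return The per-pair estimate tibble.
#' @method tidy kaks_screen
#' @export
tidy.kaks_screen <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "kaks_screen")
  attr(out, "summary") <- NULL
  attr(out, "errors") <- NULL
  out
}

#' @rdname tidy.kaks_screen
#' @method glance kaks_screen
#' @export
glance.kaks_screen <- function(x, ...) {
  s <- attr(x, "summary")
  tibble::tibble(n_pairs = nrow(x),
                 n_purifying = unname(s["purifying"]),
                 n_neutral = unname(s["neutral"]),
                 n_positive = unname(s["positive"]),
                 n_undefined = unname(s["undefined"]),
                 n_errors = nrow(attr(x, "errors")))
}

#' Tidy a delta-deviation distribution
#'
#' @param x A `delta_distribution`.
#' @param ... Unused.
#' @return Per-taxon tibble of deltas.
#' @method tidy delta_distribution
#' @export
tidy.delta_distribution <- function(x, ...) x$deltas

#' @rdname tidy.delta_distribution
#' @method glance delta_distribution
#' @export
glance.delta_distribution <- function(x, ...) {
  tibble::tibble(n_taxa = nrow(x$deltas), spread = x$spread,
                 bandwidth = x$bandwidth, n_excluded = x$n_excluded)
}
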