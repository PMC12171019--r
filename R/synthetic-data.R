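# Seeded generators for every input the pipeline consumes. Defaults emulate
# the study conditions of an oligotrophic, sealed-container bacterial
# community: lognormal-ish taxon abundances spread over ~3 decades, variant
# richness following d = c * A^gamma with Poisson scatter, skewed gene
# lengths in [60, 8748] bp, G+C centred on 0.663, and a small transposase
# ORF fraction carrying IS3-family COG labels.

#' Community configuration for the ORF-table generator
#'
#' @param n_taxa Number of taxa (species tags).
#' @param n_orfs Target total number of ORFs. When `richness_intercept` is
#'   `NULL` the intercept of the richness law is calibrated so the expected
#'   total ORF count equals `n_orfs`; when an explicit intercept is given
#'   the realized table size is the sum of the per-taxon richness draws and
#'   `n_orfs` only has to be `>= n_taxa`.
#' @param n_samples Number of TPM columns.
#' @param abundance_log10_range Interval of per-taxon log10 abundances on
#'   the pre-normalization scale; abundances are then rescaled to sum to
#'   1e6 so they live on the TPM scale.
#' @param richness_intercept,richness_slope Power law d = c * A^gamma giving
#'   the expected number of unique ORF variants per taxon.
#' @param richness_noise `"poisson"` scatters realized richness as
#'   Poisson(expected); `"none"` rounds the expectation (exact log-linear
#'   data up to integer rounding).
#' @param transposase_fraction Per-ORF probability of a transposase label
#'   (gene_name "transposase", COG2801 or COG2963).
#' @param transposase_tpm_share Optional target share (0..1) of each
#'   sample's TPM carried by transposase ORFs; calibrated with one pooled
#'   scaling factor before the final per-sample renormalization.
#' @param orphan_fraction Per-ORF probability of having no annotation and
#'   no gene name.
#' @param unknown_fraction Fraction of taxa with `unknown_<k>` species tags.
#' @param length_median_bp,length_sdlog Lognormal gene-length law (median in
#'   bp, sigma on the log scale), truncated by rejection to
#'   `[min_bp, max_bp]` and rounded to codon multiples.
#' @param min_bp,max_bp Gene-length truncation bounds; defaults are the
#'   extremes observed in the motivating dataset (60 and 8,748 bp).
#' @param gc_mean,gc_sd Normal G+C law, clipped to (0, 1).
#' @param sample_sdlog Per-sample lognormal jitter on taxon abundance.
#' @param orf_sdlog Per-ORF lognormal jitter on abundance within a taxon.
#' @param presence_prob Probability that a taxon is detected in a given
#'   sample (its ORFs get TPM 0 there otherwise); below 1 this produces
#'   the partial species overlap between containers that beta-diversity
#'   measures. Set to 1 for fully shared communities.
#' @param seed Integer seed; equal seeds give identical tables.
#' @return A `community_config` list, validated.
#' @export
community_config <- function(n_taxa = 160, n_orfs = 20000, n_samples = 3,
                             abundance_log10_range = c(1, 4),
                             richness_intercept = NULL, richness_slope = 0.757,
                             richness_noise = c("poisson", "none"),
                             transposase_fraction = 0.0271,
                             transposase_tpm_share = NULL,
                             orphan_fraction = 0.0595,
                             unknown_fraction = 0.6,
                             length_median_bp = 650, length_sdlog = 0.6,
                             min_bp = 60, max_bp = 8748,
                             gc_mean = 0.663, gc_sd = 0.05,
                             sample_sdlog = 0.25, orf_sdlog = 0.5,
                             presence_prob = 0.9,
                             seed = 1L) {
  richness_noise <- match.arg(richness_noise)
  cfg <- list(n_taxa = as.integer(n_taxa), n_orfs = as.integer(n_orfs),
              n_samples = as.integer(n_samples),
              abundance_log10_range = abundance_log10_range,
              richness_intercept = richness_intercept,
              richness_slope = richness_slope, richness_noise = richness_noise,
              transposase_fraction = transposase_fraction,
              transposase_tpm_share = transposase_tpm_share,
              orphan_fraction = orphan_fraction,
              unknown_fraction = unknown_fraction,
              length_median_bp = length_median_bp, length_sdlog = length_sdlog,
              min_bp = min_bp, max_bp = max_bp,
              gc_mean = gc_mean, gc_sd = gc_sd,
              sample_sdlog = sample_sdlog, orf_sdlog = orf_sdlog,
              presence_prob = presence_prob,
              seed = check_seed(seed))
  if (cfg$n_taxa < 1 || cfg$n_samples < 1) stop_deut("config", "need n_taxa >= 1 and n_samples >= 1")
  if (cfg$n_orfs < cfg$n_taxa) stop_deut("config", "n_orfs must be >= n_taxa")
  if (length(cfg$abundance_log10_range) != 2 ||
      diff(cfg$abundance_log10_range) < 0) {
    stop_deut("config", "abundance_log10_range must be an increasing interval")
  }
  if (!is.null(cfg$richness_intercept) && cfg$richness_intercept <= 0) {
    stop_deut("config", "richness_intercept must be positive")
  }
  if (cfg$transposase_fraction < 0 || cfg$transposase_fraction > 1) {
    stop_deut("config", "transposase_fraction must lie in [0,1]")
  }
  if (!is.null(cfg$transposase_tpm_share) &&
      (cfg$transposase_tpm_share <= 0 || cfg$transposase_tpm_share >= 1)) {
    stop_deut("config", "transposase_tpm_share must lie in (0,1)")
  }
  if (cfg$presence_prob <= 0 || cfg$presence_prob > 1) {
    stop_deut("config", "presence_prob must lie in (0,1]")
  }
  if (cfg$min_bp < 60 - 1e-9) stop_deut("config", "min_bp below 60 bp")
  if (cfg$max_bp > 8748 + 1e-9) stop_deut("config", "max_bp above 8748 bp")
  class(cfg) <- "community_config"
  cfg
}

#' Per-taxon abundance/richness points under the generating power law
#'
#' The primitive behind [generate_orf_table()]: draws per-taxon log10
#' abundances uniformly on `abundance_log10_range`, computes expected
#' richness `c * A^gamma`, and realizes observed richness as Poisson
#' scatter (or rounding in noiseless mode). Useful on its own for
#' estimator-recovery simulations.
#'
#' @param n_taxa Number of taxa.
#' @param c,gamma Generating intercept and slope.
#' @param abundance_log10_range Interval for log10 abundance draws.
#' @param noise `"poisson"` or `"none"`.
#' @param seed Integer seed.
#' @param normalize_abundance Rescale abundances to sum to 1e6 (TPM scale)
#'   before applying the law, as the table generator does.
#' @return Tibble: `taxon`, `A`, `d_expected`, `d_obs`.
#' @export
generate_richness_points <- function(n_taxa, c = 0.5, gamma = 0.757,
                                     abundance_log10_range = c(2.5, 4.5),
                                     noise = c("poisson", "none"), seed = 1L,
                                     normalize_abundance = FALSE) {
  noise <- match.arg(noise)
  set.seed(check_seed(seed))
  A <- 10^runif(n_taxa, abundance_log10_range[1], abundance_log10_range[2])
  if (normalize_abundance) A <- A / sum(A) * 1e6
  d_exp <- c * A^gamma
  d_obs <- if (noise == "poisson") rpois(n_taxa, d_exp) else round(d_exp)
  tibble::tibble(taxon = sprintf("taxon_%03d", seq_len(n_taxa)),
                 A = A, d_expected = d_exp, d_obs = as.integer(d_obs))
}

.gene_pool <- c("recA", "katG", "katE", "ada", "alkA", "luxA", "luxQ", "luxR",
                "luxO", "rpoB", "gyrA", "dnaK", "nifH", "ureC", "urtB", "accB",
                "alkB", "alkM", "bmaC", "soxB")

#' Generate a synthetic multi-sample ORF summary table
#'
#' Emulates the per-ORF table of a co-assembled metagenome: taxa with
#' log-spread abundances, per-taxon unique-variant counts following the
#' d = c * A^gamma richness law, skewed gene lengths, clipped-normal G+C,
#' independent Bernoulli(0.95) start/stop completeness flags, a Bernoulli
#' transposase subset labelled with IS3-family COGs, a Bernoulli orphan
#' subset with no annotations, and per-sample TPM columns normalized to
#' 1e6. Fully reproducible given `config$seed`.
#'
#' Taxon-level generating truth (abundance, expected and realized richness,
#' including taxa whose realized richness is zero and which therefore have
#' no rows) is attached as `attr(x, "taxa")`.
#'
#' @param config A [community_config()].
#' @return ORF table tibble (see [read_orf_table()] for columns) with a
#'   `taxa` attribute.
#' @export
generate_orf_table <- function(config) {
  if (!inherits(config, "community_config")) {
    stop_deut("config", "`config` must be a community_config")
  }
  set.seed(config$seed)
  n_taxa <- config$n_taxa

  # Taxon lineages; a configurable fraction carries unknown_<k> species tags.
  n_unknown <- round(config$unknown_fraction * n_taxa)
  unknown <- seq_len(n_taxa) %in% sample.int(n_taxa, n_unknown)
  phyla <- c("Pseudomonadota", "Actinobacteriota", "Bacteroidota")
  genus <- sprintf("Genus_%03d", seq_len(n_taxa))
  sp <- ifelse(unknown, sprintf("unknown_%d", cumsum(unknown)),
               sprintf("species_%03d", seq_len(n_taxa)))
  lineage <- paste("Bacteria", sample(phyla, n_taxa, replace = TRUE), genus, sp,
                   sep = ";")

  # Abundance and richness law on the TPM scale.
  A_raw <- 10^runif(n_taxa, config$abundance_log10_range[1],
                    config$abundance_log10_range[2])
  A <- A_raw / sum(A_raw) * 1e6
  c_eff <- config$richness_intercept
  if (is.null(c_eff)) c_eff <- config$n_orfs / sum(A^config$richness_slope)
  d_exp <- c_eff * A^config$richness_slope
  d_obs <- if (config$richness_noise == "poisson") rpois(n_taxa, d_exp)
           else round(d_exp)

  taxa <- tibble::tibble(taxon = lineage, species = sp, A = A,
                         d_expected = d_exp, d_obs = as.integer(d_obs),
                         zero_richness = d_obs == 0,
                         c_effective = c_eff, gamma = config$richness_slope)

  idx <- rep.int(seq_len(n_taxa), d_obs)
  n <- length(idx)
  if (n == 0) stop_deut("config", "configuration produced an empty table")

  # Gene lengths: truncated lognormal, codon-multiple.
  meanlog <- log(config$length_median_bp)
  len <- rlnorm(n, meanlog, config$length_sdlog)
  bad <- which(len < config$min_bp | len > config$max_bp)
  while (length(bad)) {
    len[bad] <- rlnorm(length(bad), meanlog, config$length_sdlog)
    bad <- bad[len[bad] < config$min_bp | len[bad] > config$max_bp]
  }
  len <- pmax(round(len / 3) * 3, config$min_bp)

  gc <- pmin(pmax(rnorm(n, config$gc_mean, config$gc_sd), 1e-3), 1 - 1e-3)
  is_tp <- runif(n) < config$transposase_fraction
  is_orphan <- !is_tp & runif(n) < config$orphan_fraction

  gene_name <- character(n)
  kegg <- character(n)
  cog <- character(n)
  pfam <- character(n)
  named <- !is_tp & !is_orphan & runif(n) < 0.5
  gene_name[named] <- sample(.gene_pool, sum(named), replace = TRUE)
  annotated <- !is_tp & !is_orphan
  kegg[annotated] <- sprintf("K%05d", sample.int(20000, sum(annotated), replace = TRUE))
  gene_name[is_tp] <- "transposase"
  cog[is_tp] <- sample(c("COG2801", "COG2963"), sum(is_tp), replace = TRUE)

  # Raw per-ORF abundance: taxon share split evenly, with per-ORF and
  # per-sample lognormal jitter, then per-sample normalization to 1e6.
  base <- A[idx] / pmax(d_obs[idx], 1)
  tpm <- matrix(0, n, config$n_samples)
  for (s in seq_len(config$n_samples)) {
    jitter_taxon <- rlnorm(n_taxa, -config$sample_sdlog^2 / 2, config$sample_sdlog)
    present <- if (config$presence_prob < 1) {
      runif(n_taxa) < config$presence_prob
    } else rep(TRUE, n_taxa)
    # never let a sample lose every taxon
    if (!any(present)) present[sample.int(n_taxa, 1)] <- TRUE
    jitter_orf <- rlnorm(n, -config$orf_sdlog^2 / 2, config$orf_sdlog)
    tpm[, s] <- base * jitter_taxon[idx] * jitter_orf * present[idx]
  }

  if (!is.null(config$transposase_tpm_share)) {
    if (!any(is_tp)) stop_deut("config", "transposase_tpm_share set but no transposase ORFs")
    share <- config$transposase_tpm_share
    t_tp <- sum(tpm[is_tp, , drop = FALSE])
    t_ot <- sum(tpm[!is_tp, , drop = FALSE])
    tpm[is_tp, ] <- tpm[is_tp, , drop = FALSE] * (share * t_ot / ((1 - share) * t_tp))
  }
  tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6

  out <- tibble::tibble(
    orf_id = sprintf("ORF_%06d", seq_len(n)),
    contig_id = sprintf("contig_%05d", idx),
    taxon = lineage[idx],
    gene_name = gene_name,
    kegg = kegg, cog = cog, pfam = pfam,
    length_bp = as.integer(len),
    has_start = runif(n) < 0.95,
    has_stop = runif(n) < 0.95,
    gc_fraction = gc
  )
  for (s in seq_len(config$n_samples)) out[[sprintf("tpm_S%d", s)]] <- tpm[, s]
  attr(out, "taxa") <- taxa
  validate_orf_table(out, "generated table")
  out
}

#' Evolve a codon-aligned sequence pair under a target omega
#'
#' An ancestor of `n_codons` uniformly drawn sense codons is copied and hit
#' with `n_events` proposed single-nucleotide substitutions at random
#' positions. A proposal creating a stop codon is rejected; otherwise it is
#' accepted with probability `omega / (1 + omega)` if nonsynonymous and
#' `1 / (1 + omega)` if synonymous, so the realized nonsynonymous-to-
#' synonymous rate ratio equals `omega` (omega = 0 accepts only synonymous
#' changes; omega = 1 is neutral).
#'
#' @param omega Target nonsynonymous/synonymous rate ratio (>= 0).
#' @param n_codons Codons in the ancestor.
#' @param n_events Number of proposed substitutions.
#' @param seed Integer seed.
#' @return Tibble with one row: `id_a`, `seq_a` (ancestor), `id_b`, `seq_b`
#'   (descendant), `n_accepted`.
#' @export
generate_codon_pair <- function(omega = 1, n_codons = 300, n_events = 60,
                                seed = 1L) {
  if (omega < 0) stop_deut("config", "omega must be non-negative")
  if (n_codons < 1) stop_deut("config", "n_codons must be positive")
  if (n_events < 0) stop_deut("config", "n_events must be non-negative")
  set.seed(check_seed(seed))
  ng <- ng_tables()
  nts <- c("A", "C", "G", "T")

  anc <- sample(ng$sense, n_codons, replace = TRUE)
  cur <- anc
  p_nonsyn <- omega / (1 + omega)
  p_syn <- 1 / (1 + omega)
  accepted <- 0L
  for (e in seq_len(n_events)) {
    ci <- sample.int(n_codons, 1)
    pos <- sample.int(3, 1)
    old <- cur[ci]
    nt <- sample(setdiff(nts, substr(old, pos, pos)), 1)
    new <- old
    substr(new, pos, pos) <- nt
    if (ng$code[[new]] == "*") next
    syn <- ng$code[[new]] == ng$code[[old]]
    if (runif(1) < (if (syn) p_syn else p_nonsyn)) {
      cur[ci] <- new
      accepted <- accepted + 1L
    }
  }
  tibble::tibble(id_a = "ancestor", seq_a = paste(anc, collapse = ""),
                 id_b = "descendant", seq_b = paste(cur, collapse = ""),
                 n_accepted = accepted)
}

#' Generate two amino-acid composition matrices with per-residue shifts
#'
#' Rows are per-sequence relative frequencies of the 20 standard amino
#' acids drawn from a Dirichlet distribution (concentration
#' `concentration * mean`), so each row lies on the simplex. Group B is
#' centred on `base` (default: roughly typical bacterial residue usage);
#' group A is centred on `base + effect_profile`, renormalized.
#'
#' @param n1,n2 Sequences in group A and group B. Defaults match a
#'   129-vs-70 two-group comparison.
#' @param effect_profile Named or ordered length-20 shift vector added to
#'   group A's expected frequencies; zero vector by default.
#' @param concentration Dirichlet concentration (larger = less row noise).
#' @param base Length-20 expected frequencies for group B.
#' @param seed Integer seed.
#' @return List of two `aa_composition` tibbles, `a` and `b` (see
#'   [composition_matrix()] for the shape).
#' @export
generate_aa_groups <- function(n1 = 129, n2 = 70,
                               effect_profile = rep(0, 20),
                               concentration = 500,
                               base = NULL, seed = 1L) {
  set.seed(check_seed(seed))
  if (is.null(base)) base <- rep(1 / 20, 20)
  base <- base / sum(base)
  if (length(effect_profile) != 20) stop_deut("config", "effect_profile must have length 20")
  mean_a <- base + effect_profile
  if (any(mean_a <= 0) || any(mean_a >= 1)) {
    stop_deut("config", "effect_profile pushes expected frequencies outside (0,1)")
  }
  mean_a <- mean_a / sum(mean_a)

  rdirichlet_rows <- function(n, alpha) {
    g <- matrix(rgamma(n * 20, shape = rep(alpha, each = n)), nrow = n)
    g / rowSums(g)
  }
  make <- function(n, mean, label, prefix) {
    m <- rdirichlet_rows(n, concentration * mean)
    colnames(m) <- AA20
    out <- tibble::as_tibble(m)
    out <- tibble::add_column(out,
                              sequence_id = sprintf("%s_%03d", prefix, seq_len(n)),
                              .before = 1)
    attr(out, "group_label") <- label
    class(out) <- c("aa_composition", class(out))
    out
  }
  list(a = make(n1, mean_a, "group_a", "a"),
       b = make(n2, base, "group_b", "b"))
}

#' Construct per-sample species presence sets with exact sizes and overlaps
#'
#' Builds 2 or 3 species sets from shared and private label pools so that
#' set sizes and pairwise intersections match the request exactly. With
#' three sets the three-way overlap defaults to the minimum pairwise
#' intersection.
#'
#' @param sizes Integer vector (length 2 or 3) of set sizes.
#' @param overlaps Pairwise intersection sizes: a single number for two
#'   sets, or `c(o12, o13, o23)` for three.
#' @param seed Integer seed (labels are shuffled for realism).
#' @return Named list of character vectors (`S1`, `S2`, ...).
#' @export
generate_presence_sets <- function(sizes, overlaps, seed = 1L) {
  set.seed(check_seed(seed))
  k <- length(sizes)
  if (!k %in% 2:3) stop_deut("config", "sizes must have length 2 or 3")
  lab <- function(n, tag) if (n > 0) sprintf("sp_%s_%04d", tag, seq_len(n)) else character()

  if (k == 2) {
    o <- overlaps[1]
    if (o > min(sizes) || o < 0) stop_deut("config", "overlap exceeds a set size")
    shared <- lab(o, "ab")
    sets <- list(S1 = c(shared, lab(sizes[1] - o, "a")),
                 S2 = c(shared, lab(sizes[2] - o, "b")))
  } else {
    if (length(overlaps) != 3) stop_deut("config", "need c(o12, o13, o23) for three sets")
    o12 <- overlaps[1]; o13 <- overlaps[2]; o23 <- overlaps[3]
    t <- min(o12, o13, o23)  # three-way overlap
    only12 <- o12 - t; only13 <- o13 - t; only23 <- o23 - t
    p1 <- sizes[1] - t - only12 - only13
    p2 <- sizes[2] - t - only12 - only23
    p3 <- sizes[3] - t - only13 - only23
    if (min(only12, only13, only23, p1, p2, p3) < 0) {
      stop_deut("config", "inconsistent sizes/overlaps")
    }
    core <- lab(t, "abc")
    s12 <- lab(only12, "ab"); s13 <- lab(only13, "ac"); s23 <- lab(only23, "bc")
    sets <- list(S1 = c(core, s12, s13, lab(p1, "a")),
                 S2 = c(core, s12, s23, lab(p2, "b")),
                 S3 = c(core, s13, s23, lab(p3, "c")))
  }
  lapply(sets, sample)
}
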