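# End-to-end orchestration: a flat text config ([section] headers,
# key = value lines) drives simulate -> stats / census / aacomp / kaks /
# richness, one output file per stage plus a JSON manifest with seeds,
# input digests and per-stage status. Reruns with the same config and
# seeds are byte-identical.

#' Read a flat run configuration
#'
#' Format: `[section]` headers followed by `key = value` lines; blank
#' lines and `#` comments ignored. Values are kept as strings; numeric
#' coercion happens where a stage needs it.
#'
#' @param path Config file path.
#' @return Named list of sections, each a named list of character values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_deut("config", sprintf("config not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      cfg[[section]][[key]] <- val
    } else {
      stop_deut("config", sprintf("cannot parse config line: '%s'", ln))
    }
  }
  cfg
}

num_or <- function(x, default) if (is.null(x)) default else as.numeric(x)

#' Run all enabled pipeline stages
#'
#' Stages run in dependency order: `simulate` (writes a synthetic ORF
#' table unless a real one is given), then `stats`, `census`, `aacomp`,
#' `kaks` and `richness`. A stage failure is recorded in the manifest and
#' later independent stages still run. All numeric outputs are TSV/JSON
#' files under `out_dir`; the manifest records seeds, md5 digests of every
#' written file, and per-stage summaries.
#'
#' @param config Path to a flat config file or a list from
#'   [read_run_config()]. Recognized sections/keys:
#'   `[global] out_dir, seed`;
#'   `[simulate] enabled, n_taxa, n_orfs, n_samples, transposase_fraction,
#'    richness_slope, ...` (any [community_config()] scalar);
#'   `[stats] enabled, include_unknowns`;
#'   `[census] enabled`; `[aacomp] enabled, group_a, group_b, alpha,
#'    correction`; `[kaks] enabled, pairs` (TSV manifest with columns
#'    id_a, file_a, id_b, file_b of two-record FASTA paths, or a single
#'    FASTA with an even number of records paired in order);
#'   `[richness] enabled, environment`.
#' @return The manifest (list), invisibly written to
#'   `<out_dir>/manifest.json`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  g <- config$global
  if (is.null(g$out_dir)) stop_deut("config", "global out_dir is required")
  out_dir <- g$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(num_or(g$seed, 1))

  manifest <- list(package_version = as.character(utils::packageVersion("deuteromics")),
                   seed = seed, stages = list(), files = list())
  enabled <- function(section) {
    s <- config[[section]]
    !is.null(s) && !is.null(s$enabled) && tolower(s$enabled) %in% c("1", "true", "yes")
  }
  record <- function(stage, status, summary = NULL, error = NULL) {
    manifest$stages[[stage]] <<- list(status = status, summary = summary,
                                      error = error)
  }
  emit <- function(name) {
    path <- file.path(out_dir, name)
    manifest$files[[name]] <<- unname(tools::md5sum(path))
    path
  }
  run_stage <- function(stage, fn) {
    if (!enabled(stage)) { record(stage, "skipped"); return(invisible(NULL)) }
    tryCatch({
      summary <- fn()
      record(stage, "ok", summary = summary)
    }, error = function(e) record(stage, "failed", error = conditionMessage(e)))
  }

  table <- NULL
  run_stage("simulate", function() {
    s <- config$simulate
    cc <- community_config(
      n_taxa = num_or(s$n_taxa, 160), n_orfs = num_or(s$n_orfs, 20000),
      n_samples = num_or(s$n_samples, 3),
      richness_slope = num_or(s$richness_slope, 0.757),
      transposase_fraction = num_or(s$transposase_fraction, 0.0271),
      orphan_fraction = num_or(s$orphan_fraction, 0.0595),
      seed = as.integer(num_or(s$seed, seed)))
    table <<- generate_orf_table(cc)
    path <- file.path(out_dir, "orf_table.tsv")
    write_orf_table(table, path)
    emit("orf_table.tsv")
    list(n_orfs = nrow(table), n_samples = length(orf_samples(table)))
  })

  load_table <- function(section) {
    s <- config[[section]]
    if (!is.null(s$table)) return(read_orf_table(s$table))
    if (is.null(table)) stop_deut("config", sprintf(
      "stage %s needs a table: enable [simulate] or set table=", section))
    table
  }

  run_stage("stats", function() {
    tb <- load_table("stats")
    inc <- tolower(config$stats$include_unknowns %||% "false") %in% c("1", "true", "yes")
    samples <- orf_samples(tb)
    wl <- weighted_gene_length(tb)
    rich <- tibble::tibble(
      sample = samples,
      richness_known = vapply(samples, function(s) species_richness(tb, s, FALSE), 0L),
      richness_all = vapply(samples, function(s) species_richness(tb, s, TRUE), 0L))
    stats_tbl <- tibble::tibble(metric = c("mean_length_bp", "sd_length_bp", "gc_weighted"),
                                value = c(wl$mean_bp, wl$sd_bp, gc_content(tb, "pooled")))
    readr::write_tsv(stats_tbl, file.path(out_dir, "stats.tsv"), progress = FALSE)
    readr::write_tsv(rich, file.path(out_dir, "richness_alpha.tsv"), progress = FALSE)
    readr::write_tsv(jaccard_matrix(tb, include_unknowns = inc),
                     file.path(out_dir, "jaccard.tsv"), progress = FALSE)
    emit("stats.tsv"); emit("richness_alpha.tsv"); emit("jaccard.tsv")
    list(mean_length_bp = wl$mean_bp)
  })

  run_stage("census", function() {
    tb <- load_table("census")
    cen <- transposase_census(tb)
    readr::write_tsv(tidy(cen), file.path(out_dir, "census.tsv"), progress = FALSE)
    emit("census.tsv")
    list(mean_count_pct = cen$mean_count_pct, mean_tpm = cen$mean_tpm)
  })

  run_stage("aacomp", function() {
    s <- config$aacomp
    if (!is.null(s$group_a) && !is.null(s$group_b)) {
      a <- composition_matrix(read_fasta(s$group_a), "group_a")
      b <- composition_matrix(read_fasta(s$group_b), "group_b")
    } else {
      grp <- generate_aa_groups(seed = as.integer(num_or(s$seed, seed)))
      a <- grp$a; b <- grp$b
    }
    res <- enrichment_test(a, b, alpha = num_or(s$alpha, 0.05),
                           correction = s$correction %||% "none")
    readr::write_tsv(tidy(res), file.path(out_dir, "aa_enrichment.tsv"),
                     progress = FALSE)
    emit("aa_enrichment.tsv")
    as.list(glance(res)[1, c("n_enriched", "n_depleted", "n_same")])
  })

  run_stage("kaks", function() {
    s <- config$kaks
    if (is.null(s$pairs)) stop_deut("config", "kaks stage needs pairs=")
    pairs <- read_kaks_pairs(s$pairs)
    res <- kaks_screen(pairs)
    readr::write_tsv(tidy(res), file.path(out_dir, "kaks.tsv"), progress = FALSE)
    emit("kaks.tsv")
    as.list(glance(res)[1, ])
  })

  run_stage("richness", function() {
    s <- config$richness
    tb <- load_table("richness")
    pts <- build_points(tb, environment_label = s$environment %||% "env")
    fit <- fit_power_law(pts)
    dd <- delta_distribution(pts, fit)
    jsonlite::write_json(
      list(c = fit$c, gamma = fit$gamma, se_c_log = fit$se_c_log,
           se_gamma = fit$se_gamma, r_squared = fit$r_squared,
           n_points = fit$n_points, n_excluded = fit$n_excluded),
      file.path(out_dir, "richness_fit.json"), auto_unbox = TRUE, digits = NA)
    readr::write_tsv(dd$kde, file.path(out_dir, "delta_kde.tsv"), progress = FALSE)
    readr::write_tsv(dd$deltas, file.path(out_dir, "delta_points.tsv"),
                     progress = FALSE)
    emit("richness_fit.json"); emit("delta_kde.tsv"); emit("delta_points.tsv")
    list(gamma = fit$gamma, n_points = fit$n_points, spread = dd$spread)
  })

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a ka/ks pair manifest
#'
#' Either a TSV with columns `id_a, file_a, id_b, file_b` naming FASTA
#' files (first record of each file used), or a single FASTA whose
#' records are paired in order (1st vs 2nd, 3rd vs 4th, ...).
#'
#' @param path Manifest TSV or FASTA path.
#' @return Tibble with columns `id_a`, `seq_a`, `id_b`, `seq_b`.
#' @export
read_kaks_pairs <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (startsWith(first, ">")) {
    recs <- read_fasta(path)
    if (nrow(recs) %% 2 != 0) stop_deut("format", "FASTA pair file has an odd record count")
    odd <- seq(1, nrow(recs), by = 2)
    return(tibble::tibble(id_a = recs$id[odd], seq_a = recs$seq[odd],
                          id_b = recs$id[odd + 1], seq_b = recs$seq[odd + 1]))
  }
  man <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("id_a", "file_a", "id_b", "file_b")
  if (!all(need %in% names(man))) {
    stop_deut("format", sprintf("pair manifest needs columns: %s",
                                paste(need, collapse = ", ")))
  }
  tibble::tibble(
    id_a = man$id_a, seq_a = vapply(man$file_a, function(f) read_fasta(f)$seq[1], ""),
    id_b = man$id_b, seq_b = vapply(man$file_b, function(f) read_fasta(f)$seq[1], ""))
}
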