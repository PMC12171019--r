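# Nei-Gojobori (1986) counting: per-codon synonymous/nonsynonymous site
# fractions, pathway-averaged difference counts between codon pairs, and
# Jukes-Cantor corrected distances. The standard genetic code comes from
# Biostrings; changes that create stop codons count as nonsynonymous for
# site counting, and pathways through stop codons are excluded (with the
# all-stopped fallback described in count_differences).

.ng <- new.env(parent = emptyenv())

ng_tables <- function() {
  if (!is.null(.ng$sites)) return(invisible(.ng))
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  sense <- codons[code != "*"]
  nts <- c("A", "C", "G", "T")

  neighbours <- function(codon) {
    out <- character(0)
    for (pos in 1:3) {
      for (nt in setdiff(nts, substr(codon, pos, pos))) {
        alt <- codon
        substr(alt, pos, pos) <- nt
        out <- c(out, alt)
      }
    }
    out
  }

  # Synonymous site fraction per sense codon: at each position, the share of
  # the 3 possible changes that preserve the amino acid (stops never do).
  s_sites <- vapply(sense, function(cd) {
    nb <- neighbours(cd)
    sum(code[nb] == code[[cd]] & code[nb] != "*") / 3
  }, numeric(1))

  # One-step classification: syn / nonsyn for a single-nt change between two
  # sense codons; NA marks steps touching a stop codon (fallback: nonsyn).
  step_syn <- function(a, b) {
    if (code[[a]] == "*" || code[[b]] == "*") return(NA)
    code[[a]] == code[[b]]
  }

  # Pathway-averaged (sd, nd) for every ordered sense-codon pair, with
  # stop-passing pathways discarded; if every pathway passes through a stop,
  # all pathways are kept with stop steps counted nonsynonymous.
  pair_counts <- function(a, b) {
    pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    k <- length(pos)
    if (k == 0) return(c(0, 0))
    perms <- switch(as.character(k),
      "1" = list(pos),
      "2" = list(pos, rev(pos)),
      "3" = lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
                   function(i) pos[i]))
    walk <- function(order) {
      cur <- a
      sd <- 0; nd <- 0; stopped <- FALSE
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(b, p, p)
        syn <- step_syn(cur, nxt)
        if (is.na(syn)) { stopped <- TRUE; nd <- nd + 1 }  # fallback count
        else if (syn) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      list(sd = sd, nd = nd, stopped = stopped)
    }
    walks <- lapply(perms, walk)
    clean <- Filter(function(w) !w$stopped, walks)
    use <- if (length(clean)) clean else walks
    c(mean(vapply(use, `[[`, 0, "sd")), mean(vapply(use, `[[`, 0, "nd")))
  }

  n_sense <- length(sense)
  SD <- matrix(0, n_sense, n_sense, dimnames = list(sense, sense))
  ND <- SD
  for (i in seq_len(n_sense)) {
    for (j in seq_len(n_sense)) {
      if (i < j) {
        cnt <- pair_counts(sense[i], sense[j])
        SD[i, j] <- SD[j, i] <- cnt[1]
        ND[i, j] <- ND[j, i] <- cnt[2]
      }
    }
  }
  .ng$code <- code
  .ng$sense <- sense
  .ng$sites <- s_sites
  .ng$SD <- SD
  .ng$ND <- ND
  invisible(.ng)
}

split_codons <- function(seq) {
  if (nchar(seq) %% 3 != 0) stop_deut("value", "sequence length not divisible by 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

check_sense <- function(codons, what = "codon") {
  ng <- ng_tables()
  bad <- codons[!codons %in% ng$sense]
  if (length(bad)) {
    stop_deut("value", sprintf("%s '%s' is not a sense codon under the standard code",
                               what, bad[1]))
  }
  invisible(codons)
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each of the three positions, the synonymous site fraction is the
#' number of the three possible single-nucleotide changes that preserve the
#' amino acid, divided by three; changes producing stop codons are counted
#' as nonsynonymous. `s + n = 3` exactly for every sense codon.
#'
#' @param codon A sense codon (3-letter string, alphabet ACGT).
#' @return Tibble with columns `codon`, `s`, `n`. Vectorized over `codon`.
#' @examples
#' count_sites("TTT") # s = 1/3
#' count_sites("GCA") # fourfold-degenerate third position: s = 1
#' @export
count_sites <- function(codon) {
  codon <- toupper(codon)
  check_sense(codon)
  ng <- ng_tables()
  s <- unname(ng$sites[codon])
  tibble::tibble(codon = codon, s = s, n = 3 - s)
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' Codons differing at one position are classified directly. For two or
#' three differences, all orderings of single-nucleotide steps are
#' enumerated; pathways passing through a stop codon are discarded and the
#' rest averaged with equal weight. If every pathway passes through a stop,
#' all pathways are kept and stop-touching steps are counted nonsynonymous.
#'
#' @param codon_a,codon_b Sense codons.
#' @return Tibble with columns `sd` and `nd` (possibly fractional).
#' @examples
#' count_differences("TTT", "GTA") # (0.5, 1.5): two pathways
#' @export
count_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  check_sense(codon_a); check_sense(codon_b)
  ng <- ng_tables()
  tibble::tibble(sd = unname(ng$SD[cbind(codon_a, codon_b)]),
                 nd = unname(ng$ND[cbind(codon_a, codon_b)]))
}

jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori (1986) ka/ks estimate for one codon-aligned pair
#'
#' Site counts `S`, `N` are the per-sequence sums of [count_sites()]
#' averaged over the two sequences; `Sd`, `Nd` accumulate pathway-averaged
#' differences per codon position. Proportions are corrected with the
#' Jukes-Cantor formula `d = -3/4 log(1 - 4p/3)` and the selection regime is
#' classified from `dN/dS` against a neutral band.
#'
#' @param seq_a,seq_b Codon-aligned nucleotide strings (equal length,
#'   multiple of 3, no internal stops).
#' @param neutral_band Ratios inside this closed interval are called
#'   `neutral`; below, `purifying`; above, `positive`. Default `c(0.9, 1.1)`
#'   operationalizes "ka/ks close to 1".
#' @param id_a,id_b Optional sequence labels carried into the result.
#' @return A one-row tibble of class `kaks_estimate`: `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `pN`, `dS`, `dN`, `ratio`, `regime`, `saturated`. `regime` is
#'   `"undefined"` when no differences exist, `"positive"` with infinite
#'   ratio when `dS = 0 < dN`, and distances are `NA` (flagged saturated)
#'   when a proportion reaches the Jukes-Cantor ceiling of 3/4.
#' @examples
#' ng86("GTTGCA", "GTAGCA") # one synonymous change: purifying
#' @export
ng86 <- function(seq_a, seq_b, neutral_band = c(0.9, 1.1),
                 id_a = "a", id_b = "b") {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) stop_deut("value", "sequences differ in length")
  if (nchar(seq_a) < 3) stop_deut("value", "need at least one codon")
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  check_sense(ca, "seq_a codon"); check_sense(cb, "seq_b codon")
  ng <- ng_tables()

  s_a <- sum(ng$sites[ca]); s_b <- sum(ng$sites[cb])
  S <- (s_a + s_b) / 2
  N <- 3 * length(ca) - S
  Sd <- sum(ng$SD[cbind(ca, cb)])
  Nd <- sum(ng$ND[cbind(ca, cb)])
  pS <- Sd / S
  pN <- Nd / N
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  saturated <- pS >= 0.75 || pN >= 0.75

  if (Sd == 0 && Nd == 0) {
    ratio <- NA_real_; regime <- "undefined"
  } else if (saturated) {
    ratio <- NA_real_; regime <- "undefined"
  } else if (dS == 0) {
    ratio <- Inf; regime <- "positive"
  } else {
    ratio <- dN / dS
    regime <- if (ratio < neutral_band[1]) "purifying"
              else if (ratio > neutral_band[2]) "positive"
              else "neutral"
  }

  out <- tibble::tibble(id_a = id_a, id_b = id_b, n_codons = length(ca),
                        S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                        dS = dS, dN = dN, ratio = ratio, regime = regime,
                        saturated = saturated)
  class(out) <- c("kaks_estimate", class(out))
  out
}

#' Batch ka/ks screen over many codon-aligned pairs
#'
#' @param pairs Tibble with columns `id_a`, `seq_a`, `id_b`, `seq_b` (one
#'   row per pre-aligned pair), e.g. built from [read_fasta()] output.
#' @param neutral_band Passed to [ng86()].
#' @return Tibble of class `kaks_screen`, one row per valid pair in input
#'   order, with regime summary counts in `attr(, "summary")` and per-pair
#'   failures collected in `attr(, "errors")` (a tibble of row / message),
#'   never raised.
#' @export
kaks_screen <- function(pairs, neutral_band = c(0.9, 1.1)) {
  rows <- vector("list", nrow(pairs))
  errs <- list()
  for (i in seq_len(nrow(pairs))) {
    res <- tryCatch(
      ng86(pairs$seq_a[i], pairs$seq_b[i], neutral_band,
           id_a = pairs$id_a[i], id_b = pairs$id_b[i]),
      error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1]] <- tibble::tibble(row = i, message = conditionMessage(res))
    } else {
      rows[[i]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(id_a = character(), id_b = character(),
                          n_codons = integer(), S = numeric(), N = numeric(),
                          Sd = numeric(), Nd = numeric(), pS = numeric(),
                          pN = numeric(), dS = numeric(), dN = numeric(),
                          ratio = numeric(), regime = character(),
                          saturated = logical())
  }
  regimes <- c("purifying", "neutral", "positive", "undefined")
  summary <- setNames(vapply(regimes, function(r) sum(out$regime == r), 0L), regimes)
  attr(out, "summary") <- summary
  attr(out, "errors") <- if (length(errs)) dplyr::bind_rows(errs) else
    tibble::tibble(row = integer(), message = character())
  class(out) <- c("kaks_screen", class(out))
  out
}
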