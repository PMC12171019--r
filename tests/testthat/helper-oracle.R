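# Independent brute-force oracle for Nei-Gojobori counting: recursive
# depth-first enumeration of every single-step pathway between two codons,
# written without reference to the package's lookup-table implementation.

.oracle_code <- Biostrings::GENETIC_CODE
.oracle_nts <- c("A", "C", "G", "T")

oracle_site_count <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(.oracle_nts, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (.oracle_code[[alt]] != "*" &&
          .oracle_code[[alt]] == .oracle_code[[codon]]) {
        s <- s + 1 / 3
      }
    }
  }
  c(s = s, n = 3 - s)
}

oracle_diff_count <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  paths <- list()
  recurse <- function(cur, remaining, sd, nd, stopped) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- c(sd = sd, nd = nd, stopped = stopped)
      return(invisible(NULL))
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      aa_cur <- .oracle_code[[cur]]
      aa_nxt <- .oracle_code[[nxt]]
      if (aa_cur == "*" || aa_nxt == "*") {
        recurse(nxt, setdiff(remaining, p), sd, nd + 1, TRUE)
      } else if (aa_cur == aa_nxt) {
        recurse(nxt, setdiff(remaining, p), sd + 1, nd, stopped)
      } else {
        recurse(nxt, setdiff(remaining, p), sd, nd + 1, stopped)
      }
    }
  }
  recurse(a, pos, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  clean <- m[m[, "stopped"] == 0, , drop = FALSE]
  use <- if (nrow(clean)) clean else m
  c(sd = mean(use[, "sd"]), nd = mean(use[, "nd"]))
}

sense_codons <- names(.oracle_code)[.oracle_code != "*"]

# Minimal well-formed ORF table for unit tests.
make_orf_table <- function(n = 4, samples = c("S1", "S2"), taxon = NULL,
                           gene_name = "", kegg = "", cog = "", pfam = "",
                           length_bp = 300L, has_start = TRUE, has_stop = TRUE,
                           gc = 0.5, tpm = NULL) {
  tb <- tibble::tibble(
    orf_id = sprintf("ORF_%03d", seq_len(n)),
    contig_id = sprintf("ctg_%03d", seq_len(n)),
    taxon = if (is.null(taxon)) rep("Bacteria;Phy;Gen;species_001", n) else taxon,
    gene_name = rep_len(gene_name, n),
    kegg = rep_len(kegg, n), cog = rep_len(cog, n), pfam = rep_len(pfam, n),
    length_bp = as.integer(rep_len(length_bp, n)),
    has_start = rep_len(has_start, n), has_stop = rep_len(has_stop, n),
    gc_fraction = rep_len(gc, n)
  )
  for (s in samples) {
    tb[[paste0("tpm_", s)]] <- if (is.null(tpm)) rep(1e6 / n, n) else rep_len(tpm, n)
  }
  tb
}
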