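# Classed conditions so callers can distinguish contract violations
# (format/integrity/value/config) from statistical degeneracies.
stop_deut <- function(class, msg, ...) {
  rlang::abort(msg, class = paste0("deuteromics_", class, "_error"), ...)
}

#' Sample identifiers of an ORF table
#'
#' ORF tables carry one `tpm_<sample>` column per sample; everything else is
#' per-ORF metadata. This extracts the sample ids in column order.
#'
#' @param table An ORF table tibble (see [read_orf_table()]).
#' @return Character vector of sample ids.
#' @export
orf_samples <- function(table) {
  cols <- grep("^tpm_", names(table), value = TRUE)
  sub("^tpm_", "", cols)
}

tpm_cols <- function(table) grep("^tpm_", names(table), value = TRUE)

# Species tag = last field of the semicolon-delimited lineage.
species_tag <- function(taxon) {
  parts <- strsplit(taxon, ";", fixed = TRUE)
  vapply(parts, function(p) if (length(p)) trimws(p[length(p)]) else "", "")
}

is_unknown_tag <- function(tag) startsWith(tag, "unknown_")

# Union of the annotation columns for each ORF, as a list of character sets.
annotation_sets <- function(table) {
  ann <- paste(table$kegg, table$cog, table$pfam, sep = ",")
  lapply(strsplit(ann, ",", fixed = TRUE), function(x) {
    x <- trimws(x)
    x[nzchar(x)]
  })
}

has_any_annotation <- function(table) {
  nzchar(trimws(table$kegg)) | nzchar(trimws(table$cog)) | nzchar(trimws(table$pfam))
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_deut("config", "`seed` must be a single integer")
  }
  as.integer(seed)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
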