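# On-disk dialect: tab-separated with header
#   ORF_ID Contig_ID Taxon Gene_name KEGG COG Pfam Length_bp Has_start
#   Has_stop GC_fraction TPM_<sample>...
# mirroring the per-ORF table a co-assembly pipeline emits. In memory the
# same columns are snake_case with TPM columns named tpm_<sample>.

.dialect_cols <- c("ORF_ID", "Contig_ID", "Taxon", "Gene_name", "KEGG", "COG",
                   "Pfam", "Length_bp", "Has_start", "Has_stop", "GC_fraction")
.internal_cols <- c("orf_id", "contig_id", "taxon", "gene_name", "kegg", "cog",
                    "pfam", "length_bp", "has_start", "has_stop", "gc_fraction")

parse_flag <- function(x, col, path) {
  out <- rep(NA, length(x))
  x0 <- tolower(trimws(as.character(x)))
  out[x0 %in% c("1", "true")] <- TRUE
  out[x0 %in% c("0", "false")] <- FALSE
  if (anyNA(out)) {
    stop_deut("format", sprintf(
      "column %s of %s contains values other than 0/1/true/false (first bad row: %d)",
      col, path, which(is.na(out))[1]))
  }
  out
}

validate_orf_table <- function(table, context = "ORF table") {
  if (anyDuplicated(table$orf_id)) {
    dup <- table$orf_id[duplicated(table$orf_id)][1]
    stop_deut("integrity", sprintf("%s: duplicate orf_id '%s'", context, dup))
  }
  if (any(table$length_bp < 3)) {
    stop_deut("value", sprintf("%s: length_bp < 3 at row %d", context,
                               which(table$length_bp < 3)[1]))
  }
  if (any(table$gc_fraction < 0 | table$gc_fraction > 1)) {
    stop_deut("value", sprintf("%s: gc_fraction outside [0,1] at row %d", context,
                               which(table$gc_fraction < 0 | table$gc_fraction > 1)[1]))
  }
  for (col in tpm_cols(table)) {
    bad <- which(table[[col]] < 0)
    if (length(bad)) {
      stop_deut("value", sprintf("%s: negative TPM in %s at row %d",
                                 context, col, bad[1]))
    }
  }
  invisible(table)
}

#' Read an ORF summary table
#'
#' Reads the tab-separated per-ORF dialect produced by co-assembly pipelines:
#' one row per predicted ORF with taxonomy (semicolon-delimited lineage,
#' species tags `unknown_<k>` for unclassified species), gene name, annotation
#' columns (KEGG / COG / Pfam, comma-separated within a cell), length in bp,
#' start/stop-codon completeness flags, G+C fraction, and one `TPM_<sample>`
#' abundance column per sample.
#'
#' @param path Path to a TSV file.
#' @return A tibble with snake_case columns (`orf_id`, ..., `gc_fraction`)
#'   and one `tpm_<sample>` column per sample. Sample ids are recovered with
#'   [orf_samples()].
#' @seealso [write_orf_table()], [normalize_tpm()]
#' @export
read_orf_table <- function(path) {
  if (!file.exists(path)) stop_deut("format", sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(.dialect_cols, names(raw))
  if (length(missing)) {
    stop_deut("format", sprintf("missing mandatory column(s): %s",
                                paste(missing, collapse = ", ")))
  }
  tpm_in <- grep("^TPM_", names(raw), value = TRUE)
  if (!length(tpm_in)) stop_deut("format", "no TPM_<sample> columns found")

  out <- tibble::tibble(
    orf_id = raw$ORF_ID,
    contig_id = raw$Contig_ID,
    taxon = raw$Taxon,
    gene_name = dplyr::coalesce(raw$Gene_name, ""),
    kegg = dplyr::coalesce(raw$KEGG, ""),
    cog = dplyr::coalesce(raw$COG, ""),
    pfam = dplyr::coalesce(raw$Pfam, ""),
    length_bp = as.integer(raw$Length_bp),
    has_start = parse_flag(raw$Has_start, "Has_start", path),
    has_stop = parse_flag(raw$Has_stop, "Has_stop", path),
    gc_fraction = as.numeric(raw$GC_fraction)
  )
  for (col in tpm_in) {
    out[[paste0("tpm_", sub("^TPM_", "", col))]] <- as.numeric(raw[[col]])
  }
  if (any(is.na(out$length_bp)) || any(out$length_bp < 0, na.rm = TRUE)) {
    stop_deut("value", sprintf("non-numeric or negative Length_bp at row %d",
                               which(is.na(out$length_bp) | out$length_bp < 0)[1]))
  }
  validate_orf_table(out, context = path)
  out
}

#' Write an ORF summary table
#'
#' Inverse of [read_orf_table()]: `write_orf_table()` then `read_orf_table()`
#' is the identity on conforming tables.
#'
#' @param table ORF table tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_orf_table <- function(table, path) {
  validate_orf_table(table)
  out <- tibble::tibble(
    ORF_ID = table$orf_id, Contig_ID = table$contig_id, Taxon = table$taxon,
    Gene_name = table$gene_name, KEGG = table$kegg, COG = table$cog,
    Pfam = table$pfam, Length_bp = table$length_bp,
    Has_start = as.integer(table$has_start), Has_stop = as.integer(table$has_stop),
    GC_fraction = table$gc_fraction
  )
  for (s in orf_samples(table)) out[[paste0("TPM_", s)]] <- table[[paste0("tpm_", s)]]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Length-normalized TPM from raw read counts
#'
#' Classic TPM: counts are divided by feature length, then scaled so each
#' sample sums to one million. This is the convention under which the sum of
#' all gene abundances in a sample equals 1e6 TPM.
#'
#' @param counts Non-negative read counts, one per ORF.
#' @param lengths Positive ORF lengths in bp, same length as `counts`.
#' @return Numeric vector of TPM values summing to 1e6.
#' @examples
#' normalize_tpm(c(10, 10), c(100, 200)) # 2:1 rate ratio
#' @export
normalize_tpm <- function(counts, lengths) {
  if (length(counts) != length(lengths)) {
    stop_deut("value", "`counts` and `lengths` must have equal length")
  }
  if (any(counts < 0)) stop_deut("value", "negative counts")
  if (any(lengths <= 0)) stop_deut("value", "non-positive lengths")
  rate <- counts / lengths
  total <- sum(rate)
  if (total <= 0) stop_deut("normalization", "all counts are zero")
  rate / total * 1e6
}

#' Read a FASTA file into a tibble
#'
#' @param path FASTA path. An empty file yields a zero-row tibble.
#' @return Tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `seq` (uppercased).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_deut("format", sprintf("file not found: %s", path))
  if (file.size(path) == 0) return(tibble::tibble(id = character(), seq = character()))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop_deut("integrity", sprintf("duplicate FASTA id '%s' in %s",
                                   ids[duplicated(ids)][1], path))
  }
  tibble::tibble(id = ids, seq = unname(toupper(as.character(set))))
}

#' Write a tibble of sequences as FASTA
#'
#' @param records Tibble with columns `id` and `seq`.
#' @param path Output path; sequences are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (anyDuplicated(records$id)) {
    stop_deut("integrity", sprintf("duplicate FASTA id '%s'",
                                   records$id[duplicated(records$id)][1]))
  }
  set <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}
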