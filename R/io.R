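# Readers/writers for the formats the pipeline touches: genome FASTA and the
# canonical cleavage-site table TSV. Coordinates are 0-based half-open
# throughout; any 1-based display is formatting only.

SITE_TABLE_COLS <- c("chrom", "start", "end", "strand", "aligned_seq",
                     "n_mismatch", "mismatch_positions", "flank5", "flank3",
                     "read_count")

#' Read a genome FASTA file
#'
#' Loads all records of a FASTA file into a named character vector of
#' uppercase chromosome sequences (class `genome_seq`). The allowed alphabet
#' is A, C, G, T, N; lowercase input is uppercased on load. Record order is
#' preserved and names must be unique.
#'
#' @param path path to a FASTA file.
#' @return a `genome_seq` object: named character vector of chromosome
#'   sequences with attribute `total_length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("empty FASTA file: ", path)
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA: line ", first, " is not a header line in ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  nm <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(nm))
    stop("duplicate chromosome names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(seqs) <- nm
  check_dna(seqs, what = "genome")
  genome_seq(seqs)
}

#' Construct a genome object from named sequences
#'
#' @param seqs named character vector of chromosome sequences (A/C/G/T/N).
#' @return a `genome_seq` object.
#' @export
genome_seq <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all chromosome sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("chromosome names must be unique")
  seqs <- toupper(seqs)
  check_dna(seqs, what = "genome")
  structure(seqs, total_length = sum(nchar(seqs)), class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("Genome with", length(x), "sequence(s),",
      format(attr(x, "total_length"), big.mark = ","), "bp total\n")
  n <- min(length(x), 6L)
  for (i in seq_len(n))
    cat(sprintf("  %-12s %s bp\n", names(x)[i],
                format(nchar(x[[i]]), big.mark = ",")))
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param genome a `genome_seq` object.
#' @param path output file path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Validate and classify a cleavage-site table
#'
#' A site table holds one row per matched genomic target: the protospacer
#' interval (0-based half-open), strand, genomic sequence aligned in
#' protospacer orientation, mismatch annotation, both 10-nt flanks in
#' protospacer orientation, and the supporting read count. A `match_class`
#' column (perfect / mismatch) is derived from `n_mismatch`.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `aligned_seq`, `n_mismatch`, `mismatch_positions`, `flank5`, `flank3`,
#'   `read_count`.
#' @param provenance free-text label (sample / enzyme / replicate).
#' @return a `site_table` (data.frame subclass).
#' @export
site_table <- function(df, provenance = "") {
  missing_cols <- setdiff(SITE_TABLE_COLS, names(df))
  if (length(missing_cols))
    stop("site table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[, union(SITE_TABLE_COLS, names(df)), drop = FALSE]
  df$chrom <- as.character(df$chrom)
  df$strand <- as.character(df$strand)
  df$aligned_seq <- toupper(as.character(df$aligned_seq))
  df$mismatch_positions <- as.character(df$mismatch_positions)
  df$mismatch_positions[is.na(df$mismatch_positions)] <- ""
  df$flank5 <- toupper(as.character(df$flank5))
  df$flank3 <- toupper(as.character(df$flank3))
  for (col in c("start", "end", "n_mismatch", "read_count")) {
    v <- df[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != as.integer(v)))
      stop("site table column '", col, "' must be integer-valued")
    df[[col]] <- as.integer(v)
  }
  if (nrow(df)) {
    if (any(df$read_count < 1L))
      stop("read_count must be >= 1 for every site")
    if (!all(df$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    if (any(nchar(df$flank5) != 10L) || any(nchar(df$flank3) != 10L))
      stop("flank5 and flank3 must be 10-mers")
    key <- paste(df$chrom, df$start, df$strand)
    if (anyDuplicated(key))
      stop("duplicate (chrom, start, strand) in site table: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  df$match_class <- ifelse(df$n_mismatch == 0L, "perfect", "mismatch")
  structure(df, provenance = provenance,
            class = c("site_table", "data.frame"))
}

#' Read a cleavage-site table TSV
#'
#' Column schema (tab-separated, header required): `chrom start end strand
#' aligned_seq n_mismatch mismatch_positions flank5 flank3 read_count`.
#' Lines starting with `#` are treated as comments. `mismatch_positions` is a
#' comma-separated list of 1-based spacer positions, empty for perfect sites.
#'
#' @param path input TSV path.
#' @param provenance free-text label attached to the table.
#' @return a `site_table`.
#' @export
read_site_table <- function(path, provenance = basename(path)) {
  if (!file.exists(path)) stop("site table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#",
                          colClasses = "character",
                          check.names = FALSE)
  missing_cols <- setdiff(SITE_TABLE_COLS, names(df))
  if (length(missing_cols))
    stop("site table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("start", "end", "n_mismatch", "read_count")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (nrow(df) && (any(is.na(v)) || any(v != floor(v))))
      stop("column '", col, "' must be integer in ", path)
    df[[col]] <- as.integer(v)
  }
  site_table(df, provenance = provenance)
}

#' Write a cleavage-site table TSV
#'
#' Writes the canonical 10-column schema; the derived `match_class` column is
#' not serialized. `write_site_table()` then `read_site_table()` round-trips
#' to an identical table.
#'
#' @param table a `site_table`.
#' @param path output path.
#' @param header_comments optional character vector written as leading
#'   `#`-prefixed comment lines (tool version, command line, seed).
#' @return `path`, invisibly.
#' @export
write_site_table <- function(table, path, header_comments = NULL) {
  stopifnot(inherits(table, "site_table"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_comments))
    writeLines(paste0("# ", header_comments), con)
  out <- as.data.frame(table)[, SITE_TABLE_COLS, drop = FALSE]
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @export
print.site_table <- function(x, ...) {
  cat("Cleavage-site table:", nrow(x), "sites (",
      sum(x$match_class == "perfect"), "perfect /",
      sum(x$match_class == "mismatch"), "mismatch ),",
      format(sum(x$read_count), big.mark = ","), "reads\n")
  if (nzchar(attr(x, "provenance") %||% ""))
    cat("Provenance:", attr(x, "provenance"), "\n")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse "8,11" -> c(8L, 11L); "" -> integer(0).
parse_mm_positions <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE),
         function(p) as.integer(p[nzchar(p)]))
}
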