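# Internal sequence helpers shared across modules.

# IUPAC degenerate-base expansion. Spacers may carry Y/R etc.; genomes may not
# (genome alphabet is {A,C,G,T,N}, and N windows are excluded, never "matched").
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Handles the full IUPAC alphabet (Y -> R and so on); vectorized.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("GTGAGCCACTGTGCCTGGCC")
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# Character matrix from equal-length strings (rows = sequences).
seq_matrix <- function(x) {
  if (!length(x)) return(matrix(character(0), nrow = 0, ncol = 0))
  w <- nchar(x)
  if (length(unique(w)) != 1L)
    stop("sequences have unequal lengths (", paste(unique(w), collapse = ", "), ")")
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = w[1], byrow = TRUE)
}

# Round half away from zero (printed percentages use this, not banker's rounding).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

check_dna <- function(x, what = "sequence", allow_iupac = FALSE) {
  pat <- if (allow_iupac) "[^ACGTRYSWKMBDHVN]" else "[^ACGTN]"
  bad <- grepl(pat, toupper(x))
  if (any(bad)) {
    kind <- if (allow_iupac) "non-IUPAC characters" else
      "characters outside the A/C/G/T/N alphabet"
    stop(what, " contains ", kind, ": ",
         paste(unique(x[bad]), collapse = ", "))
  }
  invisible(TRUE)
}

# All k-mers over ACGT in lexicographic order (used for PAM spaces; k small).
all_kmers <- function(k) {
  stopifnot(k >= 1, k <= 8)
  grids <- rev(expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE))
  do.call(paste0, rev(grids))
}

# Pattern sets for a possibly degenerate spacer: list of allowed-bases vectors.
pattern_sets <- function(spacer) {
  chars <- strsplit(toupper(spacer), "", fixed = TRUE)[[1]]
  unknown <- setdiff(chars, names(IUPAC_SETS))
  if (length(unknown))
    stop("protospacer contains non-IUPAC characters: ", paste(unknown, collapse = ", "))
  lapply(chars, function(ch) IUPAC_SETS[[ch]])
}

# Sliding-window scan of one chromosome string against a pattern-set list.
# Returns 0-based start positions and mismatch counts of windows with
# mismatches <= max_mm; windows containing N are skipped entirely.
scan_windows <- function(chrom_seq, psets, max_mm) {
  k <- length(psets)
  L <- nchar(chrom_seq)
  if (L < k) return(list(start0 = integer(0), mm = integer(0)))
  s <- strsplit(chrom_seq, "", fixed = TRUE)[[1]]
  n_win <- L - k + 1L
  mm <- integer(n_win)
  valid <- rep(TRUE, n_win)
  for (j in seq_len(k)) {
    sl <- s[j:(j + n_win - 1L)]
    mm <- mm + as.integer(!(sl %in% psets[[j]]))
    valid <- valid & sl != "N"
  }
  keep <- which(valid & mm <= max_mm)
  list(start0 = keep - 1L, mm = mm[keep])
}

# Deterministic per-stream seeds derived from one user seed (kept < 2^31).
derive_seed <- function(seed, stream) {
  x <- (as.numeric(seed) %% 1e6) * 1999 + as.numeric(stream) * 7919 + 17
  as.integer(x %% 2147483647)
}
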