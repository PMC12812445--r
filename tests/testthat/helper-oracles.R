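# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive per-character loops so they share no code path with
# the package implementations they check.

rand_genome <- function(seed, n_chrom = 1, len = 500, p_n = 0) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_chrom), function(i) {
    ch <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    if (p_n > 0) ch[runif(len) < p_n] <- "N"
    paste(ch, collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  genome_seq(seqs)
}

oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
           R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
           B = "V", V = "B", D = "H", H = "D")
  vapply(x, function(s) {
    ch <- strsplit(s, "")[[1]]
    paste(rev(unname(map[ch])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Naive double-strand k-mer count of a single query k-mer:
# plus-strand occurrences of w plus plus-strand occurrences of revcomp(w),
# counted by an explicit position loop.
oracle_kmer_count <- function(genome, w) {
  total <- 0L
  for (q in c(w, oracle_revcomp(w))) {
    for (s in unclass(genome)) {
      k <- nchar(q)
      if (nchar(s) < k) next
      for (i in seq_len(nchar(s) - k + 1)) {
        win <- substr(s, i, i + k - 1)
        if (!grepl("N", win, fixed = TRUE) && win == q) total <- total + 1L
      }
    }
  }
  total
}

# Naive Hamming-distance census over both strands.
oracle_neighborhood <- function(genome, proto, max_d) {
  counts <- integer(max_d + 1)
  for (q in c(proto, oracle_revcomp(proto))) {
    qc <- strsplit(q, "")[[1]]
    k <- length(qc)
    for (s in unclass(genome)) {
      if (nchar(s) < k) next
      for (i in seq_len(nchar(s) - k + 1)) {
        win <- strsplit(substr(s, i, i + k - 1), "")[[1]]
        if (any(win == "N")) next
        d <- sum(win != qc)
        if (d <= max_d) counts[d + 1] <- counts[d + 1] + 1L
      }
    }
  }
  names(counts) <- as.character(0:max_d)
  counts
}

# Textbook Pearson chi-square on a 2 x k table.
oracle_chisq <- function(M) {
  E <- outer(rowSums(M), colSums(M)) / sum(M)
  stat <- sum((M - E)^2 / E)
  df <- (nrow(M) - 1) * (ncol(M) - 1)
  list(chi2 = stat, p = stats::pchisq(stat, df, lower.tail = FALSE), df = df)
}

# Build a site table by hand from flank vectors (coordinates synthetic).
make_sites <- function(flank3, reads, flank5 = NULL, n_mismatch = NULL,
                       spacer_len = 20) {
  n <- length(flank3)
  if (is.null(flank5)) flank5 <- strrep("A", 10)
  flank5 <- rep_len(flank5, n)
  if (is.null(n_mismatch)) n_mismatch <- rep(0L, n)
  site_table(data.frame(
    chrom = "chrT",
    start = (seq_len(n) - 1L) * (spacer_len + 30L),
    end = (seq_len(n) - 1L) * (spacer_len + 30L) + spacer_len,
    strand = "+",
    aligned_seq = strrep("A", spacer_len),
    n_mismatch = as.integer(n_mismatch),
    mismatch_positions = ifelse(n_mismatch > 0, "1", ""),
    flank5 = flank5, flank3 = flank3,
    read_count = as.integer(reads),
    stringsAsFactors = FALSE))
}

# Background template set from flank vectors.
make_templates <- function(flank3, flank5 = NULL, spacer_len = 20) {
  n <- length(flank3)
  if (is.null(flank5)) flank5 <- strrep("A", 10)
  flank5 <- rep_len(flank5, n)
  df <- data.frame(
    chrom = "chrT",
    start = (seq_len(n) - 1L) * (spacer_len + 30L),
    end = (seq_len(n) - 1L) * (spacer_len + 30L) + spacer_len,
    strand = "+",
    aligned_seq = strrep("A", spacer_len),
    n_mismatch = 0L, mismatch_positions = "",
    flank5 = flank5, flank3 = flank3,
    read_count = NA_integer_, match_class = "perfect",
    stringsAsFactors = FALSE)
  structure(df, class = c("target_templates", "data.frame"))
}

# Random 10-mer flanks under a fixed seed.
rand_flanks <- function(seed, n, len = 10) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
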