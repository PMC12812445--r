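# Repeat-protospacer discovery: k-mer census over both strands, candidate
# filters (5' G, no homopolymer triple), flank extraction/diversity, and
# Hamming-neighborhood counting of near-match genomic sites.

#' Census of k-mer occurrences over both genome strands
#'
#' Counts every k-mer with the double-strand convention
#' `count(w) = fwd(w) + fwd(revcomp(w))`: a protospacer target exists
#' independently on each strand, so a palindromic k-mer at one locus counts
#' twice. Overlapping occurrences are all counted; windows containing N are
#' skipped.
#'
#' @param genome a `genome_seq`.
#' @param k k-mer length (1..32).
#' @return a `kmer_census`: list with `k`, `counts` (named integer vector,
#'   double-strand occurrence counts), `forward_total` (number of valid
#'   forward windows), `genome_label`.
#' @export
count_kmers <- function(genome, k) {
  stopifnot(inherits(genome, "genome_seq"), k >= 1, k <= 32)
  k <- as.integer(k)
  if (all(nchar(genome) < k)) {
    warning("k = ", k, " exceeds the length of every chromosome; empty census")
    return(structure(list(k = k, counts = integer(0), forward_total = 0L,
                          genome_label = ""), class = "kmer_census"))
  }
  fwd <- integer(0)
  forward_total <- 0L
  for (nm in names(genome)) {
    s <- genome[[nm]]
    L <- nchar(s)
    if (L < k) next
    w <- substring(s, 1:(L - k + 1L), k:L)
    w <- w[!grepl("N", w, fixed = TRUE)]
    forward_total <- forward_total + length(w)
    if (!length(w)) next
    tab <- table(w)
    cnt <- as.integer(tab)
    names(cnt) <- names(tab)
    fwd <- if (length(fwd)) {
      merged <- c(fwd, cnt)
      tapply(merged, names(merged), sum)
    } else cnt
  }
  fwd <- structure(as.integer(fwd), names = names(fwd))
  keys <- sort(unique(c(names(fwd), revcomp(names(fwd)))))
  counts <- integer(length(keys))
  names(counts) <- keys
  f <- function(w) {
    v <- fwd[w]
    v[is.na(v)] <- 0L
    as.integer(v)
  }
  counts <- f(keys) + f(revcomp(keys))
  names(counts) <- keys
  structure(list(k = k, counts = counts, forward_total = forward_total,
                 genome_label = ""),
            class = "kmer_census")
}

#' @export
print.kmer_census <- function(x, ...) {
  cat("k-mer census: k =", x$k, ",", length(x$counts), "distinct k-mers,",
      x$forward_total, "forward windows\n")
  invisible(x)
}

#' Filter k-mers to repeat-protospacer candidates
#'
#' Keeps k-mers that start with a 5' G, contain none of the homopolymer
#' triples AAA/TTT/CCC/GGG anywhere, and occur at least `min_occurrences`
#' times; sorted by descending occurrence count.
#'
#' @param census a `kmer_census`.
#' @param min_occurrences minimum double-strand occurrence count
#'   (default 1000 for genome-scale candidate reporting).
#' @return data.frame with columns `kmer`, `occurrences`, `starts_with_G`,
#'   `no_homopolymer_triple` (flags all TRUE for kept rows).
#' @export
filter_candidates <- function(census, min_occurrences = 1000L) {
  stopifnot(inherits(census, "kmer_census"))
  km <- names(census$counts)
  occ <- unname(census$counts)
  starts_g <- startsWith(km, "G")
  no_triple <- !grepl("AAA|TTT|CCC|GGG", km)
  keep <- starts_g & no_triple & occ >= min_occurrences
  out <- data.frame(kmer = km[keep], occurrences = occ[keep],
                    starts_with_G = TRUE, no_homopolymer_triple = TRUE,
                    stringsAsFactors = FALSE)
  out[order(-out$occurrences, out$kmer), , drop = FALSE]
}

# Exact occurrences of a k-mer on both strands.
# Returns data.frame(chrom, start0, strand); minus-strand rows are loci whose
# plus-strand sequence equals revcomp(kmer).
find_exact <- function(genome, kmer) {
  hits <- list()
  for (q in c("+", "-")) {
    pat <- if (q == "+") kmer else revcomp(kmer)
    psets <- pattern_sets(pat)
    for (nm in names(genome)) {
      sc <- scan_windows(genome[[nm]], psets, max_mm = 0L)
      if (length(sc$start0))
        hits[[length(hits) + 1L]] <-
          data.frame(chrom = nm, start0 = sc$start0, strand = q,
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(chrom = character(0), start0 = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

# Flanks of a hit in protospacer orientation. For a minus-strand hit the 3'
# flank is the reverse complement of the genomic bases immediately 5' of the
# hit interval, and vice versa.
flank_of_hit <- function(genome, chrom, start0, strand, k, side, flank_len) {
  s <- genome[[chrom]]
  L <- nchar(s)
  genomic_3p <- (strand == "+" && side == "three_prime") ||
                (strand == "-" && side == "five_prime")
  if (genomic_3p) {
    from <- start0 + k + 1L          # 1-based
    to <- from + flank_len - 1L
    if (to > L) return(NA_character_)
    fl <- substr(s, from, to)
  } else {
    to <- start0                      # 1-based end of upstream window
    from <- to - flank_len + 1L
    if (from < 1L) return(NA_character_)
    fl <- substr(s, from, to)
  }
  if (grepl("N", fl, fixed = TRUE)) return(NA_character_)
  if (strand == "-") revcomp(fl) else fl
}

#' Extract flanking sequences of a k-mer's occurrences
#'
#' One flank per occurrence on either strand, reported in protospacer
#' orientation. Occurrences whose flank window runs off the chromosome or
#' contains N are dropped and counted in the `n_dropped` attribute.
#'
#' @param genome a `genome_seq`.
#' @param kmer the k-mer (A/C/G/T).
#' @param side `"three_prime"` or `"five_prime"` (protospacer orientation).
#' @param flank_len flank length in bases (default 10).
#' @return character vector of flanks with attribute `n_dropped`.
#' @export
extract_flanks <- function(genome, kmer,
                           side = c("three_prime", "five_prime"),
                           flank_len = 10L) {
  side <- match.arg(side)
  kmer <- toupper(kmer)
  check_dna(kmer, "k-mer")
  k <- nchar(kmer)
  hits <- find_exact(genome, kmer)
  if (!nrow(hits)) {
    warning("k-mer ", kmer, " not found in genome")
    return(structure(character(0), n_dropped = 0L))
  }
  fl <- mapply(flank_of_hit, hits$chrom, hits$start0, hits$strand,
               MoreArgs = list(genome = genome, k = k, side = side,
                               flank_len = as.integer(flank_len)),
               USE.NAMES = FALSE)
  dropped <- sum(is.na(fl))
  structure(fl[!is.na(fl)], n_dropped = dropped)
}

#' Position frequency matrix and mean entropy of a flank set
#'
#' @param flanks character vector of equal-length flanks.
#' @return list with `pfm` (4 x W matrix, columns sum to 1, rows A/C/G/T) and
#'   `mean_entropy` (mean per-position Shannon entropy in bits, 0..2).
#' @export
flank_diversity <- function(flanks) {
  if (!length(flanks)) stop("need at least one flank")
  m <- seq_matrix(toupper(flanks))
  pfm <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(factor(m[, j], levels = DNA_BASES))
    as.numeric(tab) / nrow(m)
  }, numeric(4))
  pfm <- matrix(pfm, nrow = 4, dimnames = list(DNA_BASES, NULL))
  ent <- apply(pfm, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  list(pfm = pfm, mean_entropy = mean(ent))
}

#' Full repeat-candidate profile for one k-mer
#'
#' Occurrence count plus per-side flank frequency matrices and entropies, and
#' the candidate filter flags.
#'
#' @param genome a `genome_seq`.
#' @param kmer candidate k-mer.
#' @param flank_len flank length (default 10).
#' @return a `repeat_candidate` list.
#' @export
repeat_candidate <- function(genome, kmer, flank_len = 10L) {
  kmer <- toupper(kmer)
  f3 <- extract_flanks(genome, kmer, "three_prime", flank_len)
  f5 <- extract_flanks(genome, kmer, "five_prime", flank_len)
  d3 <- if (length(f3)) flank_diversity(f3) else list(pfm = NULL, mean_entropy = NA_real_)
  d5 <- if (length(f5)) flank_diversity(f5) else list(pfm = NULL, mean_entropy = NA_real_)
  structure(list(
    kmer = kmer,
    occurrences = nrow(find_exact(genome, kmer)),
    flank3_pfm = d3$pfm, flank5_pfm = d5$pfm,
    flank_entropy_3p = d3$mean_entropy, flank_entropy_5p = d5$mean_entropy,
    passes_filters = c(starts_with_G = startsWith(kmer, "G"),
                       no_homopolymer_triple = !grepl("AAA|TTT|CCC|GGG", kmer))
  ), class = "repeat_candidate")
}

#' Count genomic sites by exact Hamming distance from a protospacer
#'
#' Scans every window on both strands (windows containing N skipped) and bins
#' counts by exact substitution distance 0..`max_d`. The distance-0 bin
#' reproduces [count_kmers()] for the protospacer.
#'
#' @param genome a `genome_seq`.
#' @param protospacer the query sequence (A/C/G/T).
#' @param max_d maximum distance to tabulate (default 4).
#' @return a `mismatch_census`: list with `protospacer`, `max_d`,
#'   `counts_by_distance` (named integer vector "0".."max_d").
#' @export
mismatch_neighborhood <- function(genome, protospacer, max_d = 4L) {
  protospacer <- toupper(protospacer)
  check_dna(protospacer, "protospacer")
  max_d <- as.integer(max_d)
  stopifnot(max_d >= 0, max_d <= nchar(protospacer))
  counts <- integer(max_d + 1L)
  for (pat in c(protospacer, revcomp(protospacer))) {
    psets <- pattern_sets(pat)
    for (nm in names(genome)) {
      sc <- scan_windows(genome[[nm]], psets, max_mm = max_d)
      if (length(sc$mm))
        counts <- counts + tabulate(sc$mm + 1L, nbins = max_d + 1L)
    }
  }
  names(counts) <- as.character(0:max_d)
  structure(list(protospacer = protospacer, max_d = max_d,
                 counts_by_distance = counts),
            class = "mismatch_census")
}

#' @export
print.mismatch_census <- function(x, ...) {
  cat("Hamming neighborhood of", x$protospacer, "\n")
  print(x$counts_by_distance)
  invisible(x)
}
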