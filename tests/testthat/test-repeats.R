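# k-mer census, candidate filters, flank extraction/diversity, and the
# Hamming neighborhood, checked against naive brute-force oracles.

test_that("census follows the double-strand convention on frozen examples", {
  # counts(w) = fwd(w) + fwd(revcomp(w)), computed by the brute-force oracle
  cen <- count_kmers(genome_seq(c(c1 = "AAC")), 2)
  expect_identical(cen$counts, c(AA = 1L, AC = 1L, GT = 1L, TT = 1L))
  # palindrome: one locus counts once per strand
  expect_identical(count_kmers(genome_seq(c(c1 = "ACGT")), 4)$counts,
                   c(ACGT = 2L))
  # N excludes the window entirely
  expect_length(count_kmers(genome_seq(c(c1 = "ANC")), 2)$counts, 0)
  expect_warning(count_kmers(genome_seq(c(c1 = "ACG")), 8), "exceeds")
})

test_that("census equals the brute-force double-strand oracle", {
  for (seed in 1:8) {
    g <- rand_genome(seed, n_chrom = 1 + seed %% 2, len = 120 + 40 * seed,
                     p_n = ifelse(seed %% 3 == 0, 0.02, 0))
    k <- 2 + seed %% 4
    cen <- count_kmers(g, k)
    set.seed(seed)
    for (w in sample(names(cen$counts), min(12, length(cen$counts))))
      expect_identical(unname(cen$counts[w]), oracle_kmer_count(g, w),
                       label = paste("seed", seed, "kmer", w))
    # total forward windows identity
    expect_identical(sum(cen$counts), 2L * cen$forward_total)
  }
})

test_that("candidate filters keep 5'-G, triple-free, frequent k-mers", {
  cen <- structure(list(
    k = 20L,
    counts = c(GTGAGCCACTGTGCCTGGCC = 8471L,   # starts G, no triple: kept
               GAAAGCCACTGTGCCTGGCC = 9000L,   # AAA: rejected
               ATGAGCCACTGTGCCTGGCC = 9000L,   # no 5' G: rejected
               GTGAGCCACTGTGCCTGGCA = 10L),    # below threshold
    forward_total = 0L, genome_label = ""), class = "kmer_census")
  out <- filter_candidates(cen, min_occurrences = 1000)
  expect_identical(out$kmer, "GTGAGCCACTGTGCCTGGCC")
  expect_identical(out$occurrences, 8471L)
  # descending order by occurrences
  cen$counts <- c(GTCAGTCAGT = 5L, GACGACGACG = 50L)
  names(cen$counts) <- c("GTCAGTCAGT", "GACGACGACG")
  out2 <- filter_candidates(cen, 1)
  expect_identical(out2$occurrences, c(50L, 5L))
})

test_that("flank extraction is strand-aware and boundary-safe", {
  g <- genome_seq(c(chr1 = "AATTGGCCAC"))
  expect_identical(as.character(extract_flanks(g, "TTGG", "three_prime", 2)), "CC")
  # CCAA = revcomp(TTGG): minus-strand hit; its 3' flank is revcomp of the
  # bases 5' of the genomic interval
  expect_identical(as.character(extract_flanks(g, "CCAA", "three_prime", 2)), "TT")
  expect_identical(as.character(extract_flanks(g, "CCAA", "five_prime", 2)), "GG")
  # hit too close to the chromosome end for the flank: dropped with counter
  fl <- extract_flanks(g, "CCAC", "three_prime", 10)
  expect_length(fl, 0)
  expect_identical(attr(fl, "n_dropped"), 1L)
  expect_warning(extract_flanks(g, "GGGG", "three_prime", 2), "not found")
})

test_that("flanks of the reverse-complemented genome swap sides", {
  # a hit of k on genome g seen through (revcomp(g), revcomp(k)) flips
  # protospacer orientation: its 3' flank is the reverse complement of the
  # original 5' flank and vice versa
  g <- rand_genome(13, len = 400)
  grc <- genome_seq(c(chr1 = revcomp(g[["chr1"]])))
  km <- substr(g[["chr1"]], 101, 108)
  f3 <- sort(as.character(extract_flanks(g, km, "three_prime", 4)))
  f5 <- sort(as.character(extract_flanks(g, km, "five_prime", 4)))
  f3_rc <- sort(as.character(extract_flanks(grc, revcomp(km), "three_prime", 4)))
  f5_rc <- sort(as.character(extract_flanks(grc, revcomp(km), "five_prime", 4)))
  expect_identical(f3_rc, sort(revcomp(f5)))
  expect_identical(f5_rc, sort(revcomp(f3)))
})

test_that("flank diversity entropy spans its range correctly", {
  expect_equal(flank_diversity(c("AA", "AA"))$mean_entropy, 0)
  expect_equal(flank_diversity(c("A", "C", "G", "T"))$mean_entropy, 2)
  expect_error(flank_diversity(c("AA", "AAA")), "length")
  d <- flank_diversity(rand_flanks(5, 400))
  expect_true(all(abs(colSums(d$pfm) - 1) < 1e-9))
  expect_gt(d$mean_entropy, 1.9)
  expect_lte(d$mean_entropy, 2)
})

test_that("mismatch neighborhood matches the sliding-window oracle", {
  set.seed(21)
  g <- rand_genome(21, len = 2000)
  proto <- substr(g[["chr1"]], 501, 520)   # one planted exact copy (itself)
  mc <- mismatch_neighborhood(g, proto, max_d = 4)
  expect_identical(mc$counts_by_distance, oracle_neighborhood(g, proto, 4))
  expect_gte(mc$counts_by_distance[["0"]], 1L)
  # distance-0 bin reproduces the census count
  cen <- count_kmers(g, 20)
  expect_identical(mc$counts_by_distance[["0"]], unname(cen$counts[proto]))
})

test_that("a planted 1-substitution variant lands in the d=1 bin", {
  set.seed(33)
  base <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  proto <- "GTGAGCCACTGTGCCTGGCC"
  variant <- proto
  substr(variant, 9, 9) <- setdiff(c("A", "C", "G", "T"),
                                   substr(proto, 9, 9))[1]
  s <- paste0(substr(base, 1, 900), proto,
              substr(base, 921, 1500), variant, substr(base, 1541, 2000))
  g <- genome_seq(c(chr1 = s))
  mc <- mismatch_neighborhood(g, proto, max_d = 1)
  expect_gte(mc$counts_by_distance[["0"]], 1L)
  expect_gte(mc$counts_by_distance[["1"]], 1L)
  expect_identical(mc$counts_by_distance, oracle_neighborhood(g, proto, 1))
})

test_that("repeat candidate profile bundles occurrences, PFMs and flags", {
  g <- rand_genome(55, len = 600)
  km <- substr(g[["chr1"]], 201, 210)
  rc <- repeat_candidate(g, km, flank_len = 4)
  expect_gte(rc$occurrences, 1)
  expect_true(all(abs(colSums(rc$flank3_pfm) - 1) < 1e-9))
  expect_named(rc$passes_filters, c("starts_with_G", "no_homopolymer_triple"))
})
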