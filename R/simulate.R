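# Synthetic-data generator: planted repeat targets with i.i.d. random
# flanks, a PAM activity model deciding which planted targets are cleaved,
# overdispersed (negative binomial) read counts, and optional embedding of
# the targets in a random genome so the whole matching pipeline can be run
# against known truth.

#' PAM activity model
#'
#' A named numeric vector mapping IUPAC PAM patterns to cleavage activities
#' in [0, 1]. A 3' pattern is anchored at the spacer-proximal start of the
#' 3' flank (pattern "NGG" constrains PAM positions 1-3); a 5' pattern is
#' anchored at the spacer-proximal end of the 5' flank (pattern "TTTN"
#' constrains positions -4..-1). When several patterns match a flank the
#' most specific one (highest information content) wins.
#'
#' @param activities named numeric vector, names are IUPAC patterns.
#' @param orientation `"three_prime"` or `"five_prime"`.
#' @return a `pam_model`.
#' @export
pam_model <- function(activities,
                      orientation = c("three_prime", "five_prime")) {
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(activities), !is.null(names(activities)),
            all(activities >= 0), all(activities <= 1))
  check_dna(names(activities), "PAM pattern", allow_iupac = TRUE)
  structure(activities, orientation = orientation, class = "pam_model")
}

#' Preset PAM activity models
#'
#' Canonical models used throughout the test battery: `"NGG"` (SpCas9-like,
#' 3'), `"NNGRRT"` (SaCas9-like, 3'), `"TTTN"` (Cas12a-like, 5'),
#' `"NNNNRYAC"` (CjCas9-like long 3' PAM), `"pamless"` (no constraint).
#'
#' @param name preset name.
#' @return a `pam_model`.
#' @export
pam_model_preset <- function(name = c("NGG", "NNGRRT", "TTTN",
                                      "NNNNRYAC", "pamless")) {
  name <- match.arg(name)
  switch(name,
         NGG      = pam_model(c(NGG = 1), "three_prime"),
         NNGRRT   = pam_model(c(NNGRRT = 1), "three_prime"),
         TTTN     = pam_model(c(TTTN = 1), "five_prime"),
         NNNNRYAC = pam_model(c(NNNNRYAC = 1), "three_prime"),
         pamless  = pam_model(c(N = 1), "three_prime"))
}

# Defined (non-N) PAM positions of a model's top pattern, in reported
# coordinates: pattern index j maps to position j for a 3' PAM and to
# position j - n - 1 for a 5' PAM of pattern length n (so "TTTN" defines
# positions -4, -3, -2).
pam_model_positions <- function(model) {
  pat <- names(model)[which.max(model)]
  idx <- which(strsplit(pat, "")[[1]] != "N")
  if (attr(model, "orientation") == "three_prime") idx
  else idx - nchar(pat) - 1L
}

# Does a flank match an IUPAC pattern under the model's anchoring?
match_pattern <- function(flanks, pattern, orientation) {
  n <- nchar(pattern)
  window <- if (orientation == "three_prime") substr(flanks, 1L, n)
            else substr(flanks, nchar(flanks[1]) - n + 1L, nchar(flanks[1]))
  sets <- pattern_sets(pattern)
  m <- seq_matrix(window)
  hit <- rep(TRUE, length(flanks))
  for (j in seq_len(n)) hit <- hit & m[, j] %in% sets[[j]]
  hit
}

# information content of a pattern (bits): specificity for tie-breaking
pattern_info <- function(pattern) {
  sum(vapply(strsplit(pattern, "")[[1]],
             function(ch) log2(4 / length(IUPAC_SETS[[ch]])), numeric(1)))
}

#' Activity of PAM flanks under a model
#'
#' @param model a `pam_model`.
#' @param flank5,flank3 character vectors of 10-nt flanks in protospacer
#'   orientation.
#' @return numeric vector of activities (0 where no pattern matches).
#' @export
pam_activity <- function(model, flank5, flank3) {
  orientation <- attr(model, "orientation")
  flanks <- if (orientation == "three_prime") flank3 else flank5
  act <- numeric(length(flanks))
  spec <- rep(-Inf, length(flanks))
  for (i in seq_along(model)) {
    pat <- names(model)[i]
    hit <- match_pattern(flanks, pat, orientation)
    info <- pattern_info(pat)
    take <- hit & info > spec
    act[take] <- model[[i]]
    spec[take] <- info
  }
  act
}

#' Simulation configuration
#'
#' Bundles the study conditions of one synthetic capture experiment:
#' numbers of planted perfect and mismatch targets, the flank model
#' (i.i.d. uniform ACGT), the PAM activity model, sequencing depth and
#' overdispersion, and the capture rate.
#'
#' @param seed integer seed (all randomness derives from it).
#' @param spacer the repeat protospacer planted at every target.
#' @param n_perfect_targets planted perfect-match targets.
#' @param n_mismatch_targets planted mismatch targets (1-6 substitutions,
#'   positions biased toward spacer positions 8-11).
#' @param genome_length background genome length; default 3x the planted
#'   footprint.
#' @param pam_model a [pam_model()].
#' @param mean_depth expected reads for a fully active captured site.
#' @param dispersion negative-binomial size parameter (`Inf` for Poisson).
#' @param capture_rate probability an active site is detected at all.
#' @param mismatch_penalty per-mismatch multiplicative activity penalty.
#' @param wobble optional list(position, base, prob): among mismatch
#'   targets, force `base` at PAM `position` with probability `prob`
#'   (wobble-enrichment scenario).
#' @param flank_len flank length (default 10).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       spacer = "GTGAGCCACTGTGCCTGGCC",
                       n_perfect_targets = 2000L,
                       n_mismatch_targets = 1000L,
                       genome_length = NULL,
                       pam_model = pam_model_preset("NGG"),
                       mean_depth = 100,
                       dispersion = 2,
                       capture_rate = 0.9,
                       mismatch_penalty = 0.3,
                       wobble = NULL,
                       flank_len = 10L) {
  spacer <- toupper(spacer)
  check_dna(spacer, "spacer", allow_iupac = TRUE)
  n_total <- n_perfect_targets + n_mismatch_targets
  unit <- nchar(spacer) + 2L * flank_len
  if (is.null(genome_length)) genome_length <- n_total * unit * 3L
  if (genome_length < n_total * unit * 3L)
    stop("genome_length must be at least targets x (spacer + 2 flanks) x 3")
  stopifnot(capture_rate >= 0, capture_rate <= 1,
            mean_depth > 0, dispersion > 0,
            mismatch_penalty >= 0, mismatch_penalty <= 1)
  structure(list(seed = as.integer(seed), spacer = spacer,
                 n_perfect_targets = as.integer(n_perfect_targets),
                 n_mismatch_targets = as.integer(n_mismatch_targets),
                 genome_length = as.integer(genome_length),
                 pam_model = pam_model, mean_depth = mean_depth,
                 dispersion = dispersion, capture_rate = capture_rate,
                 mismatch_penalty = mismatch_penalty, wobble = wobble,
                 flank_len = as.integer(flank_len)),
            class = "sim_config")
}

rand_seq <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Planted-target truth table
#'
#' Draws the planted targets of a simulated experiment: aligned sequences
#' (the spacer, with substitutions for mismatch targets), strands, and
#' i.i.d. uniform random flanks. Mismatch targets carry 1-6 substitutions
#' with positions biased toward spacer positions 8-11 and counts weighted
#' toward few mismatches. Coordinates are filled in by [sim_genome()] when
#' the targets are embedded; until then `chrom`/`start` are synthetic.
#'
#' @param config a `sim_config`.
#' @return a `sim_truth` data.frame: one row per planted target with
#'   `target_id`, `chrom`, `start`, `end`, `strand`, `aligned_seq`,
#'   `n_mismatch`, `mismatch_positions`, `flank5`, `flank3`.
#' @export
sim_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  k <- nchar(config$spacer)
  n_p <- config$n_perfect_targets
  n_m <- config$n_mismatch_targets
  n <- n_p + n_m
  n_mismatch <- c(rep(0L, n_p),
                  sample(1:6, n_m, replace = TRUE,
                         prob = c(0.4, 0.25, 0.15, 0.1, 0.06, 0.04)))
  pos_w <- rep(1, k)
  pos_w[intersect(8:11, seq_len(k))] <- 4
  # concrete spacer instance per target (degenerate positions drawn i.i.d.)
  sets <- pattern_sets(config$spacer)
  sp_mat <- matrix(rep(vapply(sets, `[`, "", 1), each = n), nrow = n)
  for (j in which(lengths(sets) > 1))
    sp_mat[, j] <- sample(sets[[j]], n, replace = TRUE)
  mm_pos <- character(n)
  for (i in which(n_mismatch > 0)) {
    pos <- sort(sample(seq_len(k), n_mismatch[i], prob = pos_w))
    for (p in pos)
      sp_mat[i, p] <- sample(setdiff(DNA_BASES, sp_mat[i, p]), 1)
    mm_pos[i] <- paste(pos, collapse = ",")
  }
  aligned <- do.call(paste0, as.data.frame(sp_mat, stringsAsFactors = FALSE))
  flank5 <- rand_seq(n, config$flank_len)
  flank3 <- rand_seq(n, config$flank_len)
  if (!is.null(config$wobble)) {
    wb <- config$wobble
    orientation <- attr(config$pam_model, "orientation")
    idx <- pam_position_index(wb$position, orientation)
    force_rows <- which(n_mismatch > 0 & stats::runif(n) < wb$prob)
    if (orientation == "three_prime") {
      substr(flank3[force_rows], idx, idx) <- wb$base
    } else {
      substr(flank5[force_rows], idx, idx) <- wb$base
    }
  }
  unit <- k + 2L * config$flank_len
  structure(data.frame(
    target_id = seq_len(n),
    chrom = "sim",
    start = (seq_len(n) - 1L) * (unit + 10L) + config$flank_len,
    end = (seq_len(n) - 1L) * (unit + 10L) + config$flank_len + k,
    strand = sample(c("+", "-"), n, replace = TRUE),
    aligned_seq = aligned,
    n_mismatch = n_mismatch,
    mismatch_positions = mm_pos,
    flank5 = flank5, flank3 = flank3,
    stringsAsFactors = FALSE),
    spacer = config$spacer, placed = FALSE,
    class = c("sim_truth", "data.frame"))
}

#' Embed planted targets in a random genome
#'
#' Builds an i.i.d. random background sequence and plants each target's
#' flank5 + aligned sequence + flank3 cassette (reverse-complemented for
#' minus-strand targets) at non-overlapping positions: the chromosome is
#' divided into equal slots, one target per slot at a random offset, which
#' guarantees placement succeeds. Truth coordinates are updated to the
#' protospacer interval (0-based half-open).
#'
#' @param config a `sim_config`.
#' @param truth optional pre-drawn [sim_truth()] (drawn from `config` when
#'   omitted).
#' @return list with `genome` (a `genome_seq`, one chromosome `chr1`) and
#'   `truth` (coordinates filled in).
#' @export
sim_genome <- function(config, truth = sim_truth(config)) {
  set.seed(derive_seed(config$seed, 2L))
  L <- config$genome_length
  n <- nrow(truth)
  k <- nchar(config$spacer)
  unit <- k + 2L * config$flank_len
  slot_w <- L %/% n
  if (slot_w < unit + 2L)
    stop("cannot place ", n, " non-overlapping targets in ", L, " bases")
  chars <- sample(DNA_BASES, L, replace = TRUE)
  offsets <- sample.int(slot_w - unit + 1L, n, replace = TRUE) - 1L
  slot_starts <- (seq_len(n) - 1L) * slot_w
  cassette <- paste0(truth$flank5, truth$aligned_seq, truth$flank3)
  cassette <- ifelse(truth$strand == "-", revcomp(cassette), cassette)
  for (i in seq_len(n)) {
    s0 <- slot_starts[i] + offsets[i]           # 0-based cassette start
    chars[(s0 + 1L):(s0 + unit)] <- strsplit(cassette[i], "")[[1]]
  }
  truth$chrom <- "chr1"
  # protospacer interval within the cassette: flank_len bases in from the
  # cassette start on the plus strand regardless of target strand
  cass_start <- slot_starts + offsets
  truth$start <- cass_start + config$flank_len
  truth$end <- truth$start + k
  attr(truth, "placed") <- TRUE
  genome <- genome_seq(c(chr1 = paste(chars, collapse = "")))
  list(genome = genome, truth = truth)
}

# zero-truncated negative binomial (or Poisson at dispersion = Inf)
rztnb <- function(n, mu, size) {
  if (!n) return(integer(0))
  if (is.infinite(size)) {
    p0 <- stats::dpois(0, mu)
    u <- p0 + stats::runif(n) * (1 - p0)
    return(stats::qpois(u, mu))
  }
  p0 <- stats::pnbinom(0, size = size, mu = mu)
  u <- p0 + stats::runif(n) * (1 - p0)
  stats::qnbinom(u, size = size, mu = mu)
}

#' Simulate PAM-dependent capture of planted targets
#'
#' Each planted target receives an activity from the PAM model applied to
#' its PAM-side flank, multiplied by `mismatch_penalty` per mismatch.
#' Active sites are detected with probability `capture_rate`; detected
#' sites draw a zero-truncated negative-binomial read count with mean
#' activity x `mean_depth` and size `dispersion`.
#'
#' @param truth a [sim_truth()] table.
#' @param config the `sim_config` (PAM model, depth, dispersion, capture
#'   rate, penalty, seed).
#' @return a [site_table()] of detected sites; the truth table with
#'   `activity` and `realized_reads` columns is in the `truth` attribute.
#' @export
sim_capture <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 3L))
  n <- nrow(truth)
  act <- pam_activity(config$pam_model, truth$flank5, truth$flank3) *
    config$mismatch_penalty^truth$n_mismatch
  detected <- stats::runif(n) < config$capture_rate * (act > 0)
  reads <- integer(n)
  reads[detected] <- rztnb(sum(detected), mu = act[detected] * config$mean_depth,
                           size = config$dispersion)
  truth$activity <- act
  truth$realized_reads <- reads
  emit <- which(reads > 0)
  df <- data.frame(
    chrom = truth$chrom[emit], start = truth$start[emit],
    end = truth$end[emit], strand = truth$strand[emit],
    aligned_seq = truth$aligned_seq[emit],
    n_mismatch = truth$n_mismatch[emit],
    mismatch_positions = truth$mismatch_positions[emit],
    flank5 = truth$flank5[emit], flank3 = truth$flank3[emit],
    read_count = reads[emit], stringsAsFactors = FALSE)
  tab <- site_table(df, provenance = sprintf("sim(seed=%d)", config$seed))
  attr(tab, "truth") <- truth
  tab
}

#' Planted targets as a background template set
#'
#' The planted-target table in the column layout of
#' [find_genomic_targets()] output, for use as the genomic background of
#' PCV and motif-table computations. On a clean synthetic genome,
#' `find_genomic_targets()` recovers exactly this set at `max_mm = 0` (plus
#' chance background hits at larger budgets).
#'
#' @param truth a [sim_truth()] table.
#' @return a `target_templates` data.frame.
#' @export
sim_templates <- function(truth) {
  df <- data.frame(
    chrom = truth$chrom, start = truth$start, end = truth$end,
    strand = truth$strand, aligned_seq = truth$aligned_seq,
    n_mismatch = truth$n_mismatch,
    mismatch_positions = truth$mismatch_positions,
    flank5 = truth$flank5, flank3 = truth$flank3,
    read_count = NA_integer_, stringsAsFactors = FALSE)
  df$match_class <- ifelse(df$n_mismatch == 0L, "perfect", "mismatch")
  structure(df, protospacer = attr(truth, "spacer"),
            class = c("target_templates", "data.frame"))
}
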