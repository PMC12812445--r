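# Cross-enzyme / cross-cell-line comparisons: on/off-target ratios,
# read-downsampling discovery curves, relative activity and specificity,
# and chromosomal-window cleavage profiles.

#' On/off-target summary of a site table
#'
#' @param sites a `site_table`.
#' @param label enzyme / sample label.
#' @return one-row data.frame (`enzyme_summary`): `label`, `n_on_sites`,
#'   `n_off_sites`, `on_reads`, `off_reads`, `site_ratio`, `read_ratio`.
#'   Ratios with zero denominators are `NA` (undefined, not infinite).
#' @export
enzyme_summary <- function(sites, label = attr(sites, "provenance") %||% "") {
  if (!nrow(sites)) stop("site table is empty")
  on <- sites$match_class == "perfect"
  n_on <- sum(on); n_off <- sum(!on)
  on_reads <- sum(sites$read_count[on])
  off_reads <- sum(sites$read_count[!on])
  structure(data.frame(
    label = label, n_on_sites = n_on, n_off_sites = n_off,
    on_reads = on_reads, off_reads = off_reads,
    site_ratio = if (n_off > 0) n_on / n_off else NA_real_,
    read_ratio = if (off_reads > 0) on_reads / off_reads else NA_real_,
    stringsAsFactors = FALSE),
    class = c("enzyme_summary", "data.frame"))
}

#' Relative activity and specificity across enzymes
#'
#' Relative activity is the number of perfect-match sites relative to the
#' reference wild-type enzyme; relative specificity is the
#' perfect-to-mismatch site ratio relative to the high-fidelity reference
#' enzyme. Each reference's own relative metric is 1.
#'
#' @param summaries data.frame of stacked [enzyme_summary()] rows.
#' @param wt_label label of the activity reference (wild-type-like).
#' @param specificity_ref_label label of the specificity reference
#'   (high-fidelity-like).
#' @return data.frame with `label`, `relative_activity`,
#'   `relative_specificity` (scatter-ready).
#' @export
activity_specificity <- function(summaries, wt_label, specificity_ref_label) {
  need <- c(wt_label, specificity_ref_label)
  missing_ref <- setdiff(need, summaries$label)
  if (length(missing_ref))
    stop("reference label(s) not present: ", paste(missing_ref, collapse = ", "))
  wt_on <- summaries$n_on_sites[summaries$label == wt_label][1]
  ref_ratio <- summaries$site_ratio[summaries$label == specificity_ref_label][1]
  if (is.na(wt_on) || wt_on == 0) stop("activity reference has no perfect-match sites")
  if (is.na(ref_ratio) || ref_ratio == 0)
    stop("specificity reference has an undefined or zero on/off ratio")
  data.frame(label = summaries$label,
             relative_activity = summaries$n_on_sites / wt_on,
             relative_specificity = summaries$site_ratio / ref_ratio,
             stringsAsFactors = FALSE)
}

#' Read-downsampling site-discovery curve
#'
#' Draws reads without replacement from the site-by-read-count multiset
#' (multivariate hypergeometric at each depth) and counts sites detected
#' with at least `min_reads` sampled reads, averaged over replicates. Each
#' replicate draws one random permutation of the read multiset so per-depth
#' counts are prefix sums of a single draw (nested subsamples).
#'
#' @param sites a `site_table`.
#' @param depths numeric vector of read totals to sample down to.
#' @param n_reps number of Monte Carlo replicates (default 100).
#' @param seed integer seed; per-replicate streams derive from it.
#' @param min_reads detection threshold (default 1 sampled read).
#' @param replace sample with replacement (permits depths above the total).
#' @return data.frame: `depth`, `mean_on_sites`, `mean_off_sites`,
#'   `mean_total_sites`, `sd_total_sites`.
#' @export
downsample_curve <- function(sites, depths, n_reps = 100L, seed = 1L,
                             min_reads = 1L, replace = FALSE) {
  total <- sum(sites$read_count)
  depths <- as.integer(depths)
  if (!replace && any(depths > total))
    stop("depth exceeds total reads (", total,
         "); use replace = TRUE to sample with replacement")
  ids <- rep.int(seq_len(nrow(sites)), sites$read_count)
  on <- sites$match_class == "perfect"
  on_mat <- matrix(0, n_reps, length(depths))
  off_mat <- matrix(0, n_reps, length(depths))
  for (rep_i in seq_len(n_reps)) {
    set.seed(derive_seed(seed, rep_i))
    perm <- if (replace) NULL else sample(ids, length(ids))
    for (di in seq_along(depths)) {
      d <- depths[di]
      drawn <- if (replace) sample(ids, d, replace = TRUE) else perm[seq_len(d)]
      det <- tabulate(drawn, nbins = nrow(sites)) >= min_reads
      on_mat[rep_i, di] <- sum(det & on)
      off_mat[rep_i, di] <- sum(det & !on)
    }
  }
  tot_mat <- on_mat + off_mat
  data.frame(depth = depths,
             mean_on_sites = colMeans(on_mat),
             mean_off_sites = colMeans(off_mat),
             mean_total_sites = colMeans(tot_mat),
             sd_total_sites = apply(tot_mat, 2, stats::sd))
}

#' Per-window cleavage-read proportions
#'
#' Splits each chromosome into fixed-size windows (the last window may be
#' short), assigns each site's reads to the window containing its
#' protospacer start, and normalizes to proportions summing to 1.
#'
#' @param sites a `site_table`.
#' @param genome_lengths named numeric vector of chromosome lengths.
#' @param window window size in bases (default 5e6).
#' @return a `window_profile` data.frame: `chrom`, `win_index` (0-based),
#'   `start`, `end`, `reads`, `proportion`.
#' @export
window_profile <- function(sites, genome_lengths, window = 5e6) {
  stopifnot(!is.null(names(genome_lengths)))
  unknown <- setdiff(unique(sites$chrom), names(genome_lengths))
  if (length(unknown))
    stop("sites on chromosomes without a known length: ",
         paste(unknown, collapse = ", "))
  window <- as.numeric(window)
  grid <- do.call(rbind, lapply(names(genome_lengths), function(nm) {
    n_win <- max(1L, as.integer(ceiling(genome_lengths[[nm]] / window)))
    idx <- seq_len(n_win) - 1L
    data.frame(chrom = nm, win_index = idx,
               start = idx * window,
               end = pmin((idx + 1) * window, genome_lengths[[nm]]),
               stringsAsFactors = FALSE)
  }))
  key_grid <- paste(grid$chrom, grid$win_index)
  site_key <- paste(sites$chrom, floor(sites$start / window))
  reads <- vapply(key_grid, function(kk)
    sum(sites$read_count[site_key == kk]), numeric(1), USE.NAMES = FALSE)
  grid$reads <- reads
  total <- sum(reads)
  if (total == 0) stop("no reads fall in any window")
  grid$proportion <- reads / total
  structure(grid, window = window,
            class = c("window_profile", "data.frame"))
}

#' Log2 ratio of a window profile against reference replicates
#'
#' The reference is the arithmetic mean of the replicate profiles'
#' per-window proportions; the ratio is log2(sample / reference), `NA` where
#' the reference proportion is zero.
#'
#' @param sample a `window_profile`.
#' @param reference_replicates a `window_profile` or list of them
#'   (replicates on the same window grid).
#' @return the sample profile with `ref_proportion` and `log2_ratio`
#'   columns added.
#' @export
profile_ratio <- function(sample, reference_replicates) {
  if (inherits(reference_replicates, "window_profile"))
    reference_replicates <- list(reference_replicates)
  stopifnot(length(reference_replicates) >= 1)
  key <- paste(sample$chrom, sample$win_index)
  ref_mat <- vapply(reference_replicates, function(r) {
    rk <- paste(r$chrom, r$win_index)
    if (!identical(rk, key))
      stop("reference replicate is not on the same window grid")
    r$proportion
  }, numeric(nrow(sample)))
  ref_mean <- rowMeans(as.matrix(ref_mat))
  out <- as.data.frame(sample)
  out$ref_proportion <- ref_mean
  out$log2_ratio <- ifelse(ref_mean > 0,
                           log2(out$proportion / ref_mean), NA_real_)
  structure(out, window = attr(sample, "window"),
            class = c("window_profile", "data.frame"))
}
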