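# PAM preference summaries: read-weighted position frequency matrices,
# PAM cleavage values (PCV) against a genomic background, the 4-base
# heat-map grid, and the wobble-base stratified comparison.

#' Read-weighted position frequency matrix of PAM flanks
#'
#' Frequency of base b at PAM position j is the weight (read counts by
#' default) of sites carrying b at j divided by the total weight, optionally
#' stratified by perfect-match vs mismatch sites.
#'
#' @param sites a `site_table`.
#' @param orientation `"three_prime"` or `"five_prime"`.
#' @param stratum `"all"`, `"perfect"`, or `"mismatch"`.
#' @param weight_mode `"reads"` (read-count weights) or `"sites"` (each site
#'   weighted 1).
#' @return a `weighted_pfm`: list with `matrix` (4 x W, columns sum to 1,
#'   column names are PAM positions), `stratum`, `weights_used`, `n_sites`,
#'   `total_reads`.
#' @export
weighted_pfm <- function(sites, orientation = c("three_prime", "five_prime"),
                         stratum = c("all", "perfect", "mismatch"),
                         weight_mode = c("reads", "sites")) {
  orientation <- match.arg(orientation)
  stratum <- match.arg(stratum)
  weight_mode <- match.arg(weight_mode)
  rows <- if (stratum == "all") seq_len(nrow(sites)) else
    which(sites$match_class == stratum)
  if (!length(rows))
    stop("no sites in stratum '", stratum, "'")
  flanks <- pam_flank(sites[rows, , drop = FALSE], orientation)
  w <- if (weight_mode == "reads") as.numeric(sites$read_count[rows])
       else rep(1, length(rows))
  m <- seq_matrix(flanks)
  W <- ncol(m)
  pfm <- vapply(seq_len(W), function(j) {
    vapply(DNA_BASES, function(b) sum(w[m[, j] == b]), numeric(1)) / sum(w)
  }, numeric(4))
  pfm <- matrix(pfm, nrow = 4,
                dimnames = list(DNA_BASES,
                                pam_index_position(seq_len(W), orientation)))
  structure(list(matrix = pfm, stratum = stratum, weights_used = weight_mode,
                 orientation = orientation, n_sites = length(rows),
                 total_reads = sum(sites$read_count[rows])),
            class = "weighted_pfm")
}

#' @export
print.weighted_pfm <- function(x, digits = 3, ...) {
  cat("Weighted PFM (", x$stratum, " sites, weights = ", x$weights_used,
      "): ", x$n_sites, " sites, ", x$total_reads, " reads\n", sep = "")
  print(round(x$matrix, digits))
  invisible(x)
}

#' PAM cleavage value (PCV) table
#'
#' For each PAM sequence of length `L` in the scored window, PCV is the
#' fraction of that sequence among all captured PAM windows (read-weighted by
#' default) divided by its fraction among the background population of
#' genomic target flanks. The relative PCV is log2(PCV) normalized so the
#' highest-PCV PAM is 0; a PAM captured zero times has relative PCV -Inf,
#' and a PAM absent from the background has undefined PCV (flagged, not
#' infinite).
#'
#' @param sites a `site_table` (the captured sites).
#' @param background_pams character vector: the PAM flank population of all
#'   candidate genomic targets (10-mers, or already-sliced L-mers).
#' @param L PAM length to score (<= 10).
#' @param orientation `"three_prime"` or `"five_prime"`.
#' @param window_offset which L consecutive PAM positions to score, counted
#'   from the spacer-proximal end (default 1: positions 1..L for a 3' PAM,
#'   -L..-1 for a 5' PAM).
#' @param weight_mode `"reads"` or `"sites"` for the captured fractions.
#' @return a `pcv_table` data.frame: `pam`, `captured_fraction`,
#'   `background_fraction`, `pcv`, `relative_pcv`, `undefined`.
#' @export
pcv_table <- function(sites, background_pams, L,
                      orientation = c("three_prime", "five_prime"),
                      window_offset = 1L,
                      weight_mode = c("reads", "sites")) {
  orientation <- match.arg(orientation)
  weight_mode <- match.arg(weight_mode)
  L <- as.integer(L)
  stopifnot(L >= 1, L <= 10)
  if (!length(background_pams)) stop("background PAM population is empty")
  cap_full <- pam_flank(sites, orientation)
  cap <- if (nchar(cap_full[1]) > L)
    pam_window_slice(cap_full, orientation, window_offset, L) else cap_full
  bg <- if (nchar(background_pams[1]) > L)
    pam_window_slice(background_pams, orientation, window_offset, L)
    else background_pams
  if (any(nchar(bg) != L)) stop("background PAMs must have length ", L)
  w <- if (weight_mode == "reads") as.numeric(sites$read_count) else
    rep(1, nrow(sites))
  cap_w <- tapply(w, cap, sum)
  bg_t <- table(bg)
  pams <- sort(unique(c(names(cap_w), names(bg_t))))
  cf <- as.numeric(cap_w[pams]); cf[is.na(cf)] <- 0
  cf <- cf / sum(w)
  bf <- as.numeric(bg_t[pams]); bf[is.na(bf)] <- 0
  bf <- bf / length(bg)
  pcv <- ifelse(bf > 0, cf / bf, NA_real_)
  undefined <- bf == 0
  maxp <- max(pcv, na.rm = TRUE)
  rel <- ifelse(is.na(pcv), NA_real_,
                ifelse(pcv > 0, log2(pcv / maxp), -Inf))
  out <- data.frame(pam = pams, captured_fraction = cf,
                    background_fraction = bf, pcv = pcv,
                    relative_pcv = rel, undefined = undefined,
                    stringsAsFactors = FALSE)
  structure(out, L = L, orientation = orientation,
            window_offset = as.integer(window_offset),
            weight_mode = weight_mode,
            class = c("pcv_table", "data.frame"))
}

#' 4-base heat-map grid of relative PCV
#'
#' Reshapes a length-4 PCV table into the 16 x 16 grid used for 4-base PAM
#' heat maps: rows are the first two scored positions (AA..TT,
#' lexicographic), columns the last two. Undefined cells (background zero)
#' are `NA`; PAMs captured zero times carry `-Inf`.
#'
#' @param pcv a `pcv_table` with `L = 4`.
#' @return 16 x 16 numeric matrix of relative PCV.
#' @export
heatmap_matrix <- function(pcv) {
  stopifnot(inherits(pcv, "pcv_table"))
  if (attr(pcv, "L") != 4L) stop("heatmap_matrix requires a PCV table with L = 4")
  dn <- all_kmers(2)
  m <- matrix(NA_real_, 16, 16, dimnames = list(dn, dn))
  r <- substr(pcv$pam, 1, 2)
  c2 <- substr(pcv$pam, 3, 4)
  vals <- ifelse(pcv$undefined, NA_real_, pcv$relative_pcv)
  m[cbind(match(r, dn), match(c2, dn))] <- vals
  m
}

#' Wobble-base comparison between perfect-match and mismatch strata
#'
#' Compares the prevalence of a given base at a given PAM position between
#' perfect-match-associated and mismatch-associated PAMs: read-weighted
#' fractions per stratum plus a two-sided Pearson chi-square test on the
#' 2 x 2 site-count table (base vs not-base by perfect vs mismatch).
#'
#' @param sites a `site_table` containing both strata.
#' @param position PAM position (1..10 for 3' PAM, -10..-1 for 5' PAM).
#' @param base the base whose prevalence is compared.
#' @param orientation `"three_prime"` or `"five_prime"`.
#' @return list with `perfect_frac`, `mismatch_frac`, `chi2`, `p_value`,
#'   and the underlying 2 x 2 `counts`.
#' @export
wobble_comparison <- function(sites, position, base,
                              orientation = c("three_prime", "five_prime")) {
  orientation <- match.arg(orientation)
  base <- toupper(base)
  stopifnot(base %in% DNA_BASES)
  idx <- pam_position_index(position, orientation)
  flanks <- pam_flank(sites, orientation)
  at <- substr(flanks, idx, idx)
  strata <- split(seq_len(nrow(sites)), sites$match_class)
  if (is.null(strata$perfect) || is.null(strata$mismatch))
    stop("both perfect and mismatch strata must be nonempty")
  wfrac <- function(rows) {
    w <- as.numeric(sites$read_count[rows])
    sum(w[at[rows] == base]) / sum(w)
  }
  counts <- rbind(
    perfect = c(base = sum(at[strata$perfect] == base),
                other = sum(at[strata$perfect] != base)),
    mismatch = c(base = sum(at[strata$mismatch] == base),
                 other = sum(at[strata$mismatch] != base)))
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(perfect_frac = wfrac(strata$perfect),
       mismatch_frac = wfrac(strata$mismatch),
       chi2 = unname(ct$statistic), p_value = unname(ct$p.value),
       counts = counts)
}
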