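# Matching cleavage evidence to protospacer-aligned genomic targets:
# enumerate candidate targets within a mismatch budget, assign integration
# events to targets, and expose the PAM-side flank.

#' Enumerate candidate genomic targets of a protospacer
#'
#' Finds every genomic window on either strand within `max_mm` substitutions
#' of the protospacer (substitution-only matching; no bulges). Degenerate
#' IUPAC bases in the protospacer (e.g. Y in extended spacers) match their
#' allowed set without counting as mismatches. The PAM-side flank is not
#' constrained: both 10-nt flanks are populated for every template so the PAM
#' can be treated as unknown downstream. Windows containing N are skipped;
#' templates whose flank windows run off the chromosome or contain N are
#' dropped and counted in the `n_dropped_flank` attribute.
#'
#' @param genome a `genome_seq`.
#' @param protospacer spacer sequence over the IUPAC alphabet (typically
#'   20-22 nt).
#' @param max_mm maximum number of mismatches (default 6).
#' @param flank_len flank length (default 10).
#' @return a `target_templates` data.frame with the site-table columns
#'   (`read_count` is `NA`: templates are potential targets, not yet
#'   supported by reads) plus `match_class`.
#' @export
find_genomic_targets <- function(genome, protospacer, max_mm = 6L,
                                 flank_len = 10L) {
  protospacer <- toupper(protospacer)
  check_dna(protospacer, "protospacer", allow_iupac = TRUE)
  k <- nchar(protospacer)
  max_mm <- as.integer(max_mm)
  psets <- pattern_sets(protospacer)
  rows <- list()
  n_dropped <- 0L
  for (strand in c("+", "-")) {
    scan_sets <- if (strand == "+") psets else rev(lapply(psets, revcomp))
    for (nm in names(genome)) {
      sc <- scan_windows(genome[[nm]], scan_sets, max_mm = max_mm)
      if (!length(sc$start0)) next
      s <- genome[[nm]]
      win <- substring(s, sc$start0 + 1L, sc$start0 + k)
      aligned <- if (strand == "+") win else revcomp(win)
      # per-spacer-position mismatch annotation
      am <- seq_matrix(aligned)
      mm_mat <- matrix(FALSE, nrow = nrow(am), ncol = k)
      for (j in seq_len(k))
        mm_mat[, j] <- !(am[, j] %in% psets[[j]])
      mm_pos <- apply(mm_mat, 1, function(v)
        paste(which(v), collapse = ","))
      f5 <- mapply(flank_of_hit, nm, sc$start0, strand,
                   MoreArgs = list(genome = genome, k = k,
                                   side = "five_prime",
                                   flank_len = as.integer(flank_len)),
                   USE.NAMES = FALSE)
      f3 <- mapply(flank_of_hit, nm, sc$start0, strand,
                   MoreArgs = list(genome = genome, k = k,
                                   side = "three_prime",
                                   flank_len = as.integer(flank_len)),
                   USE.NAMES = FALSE)
      ok <- !is.na(f5) & !is.na(f3)
      n_dropped <- n_dropped + sum(!ok)
      if (!any(ok)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = nm,
        start = sc$start0[ok],
        end = sc$start0[ok] + k,
        strand = strand,
        aligned_seq = aligned[ok],
        n_mismatch = sc$mm[ok],
        mismatch_positions = mm_pos[ok],
        flank5 = f5[ok],
        flank3 = f3[ok],
        read_count = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), aligned_seq = character(0),
               n_mismatch = integer(0), mismatch_positions = character(0),
               flank5 = character(0), flank3 = character(0),
               read_count = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$match_class <- ifelse(out$n_mismatch == 0L, "perfect", "mismatch")
  structure(out, protospacer = protospacer, max_mm = max_mm,
            n_dropped_flank = n_dropped,
            class = c("target_templates", "data.frame"))
}

#' Assign dsODN-style integration events to candidate targets
#'
#' Each event (an integration position with a read count) is assigned to the
#' nearest template whose protospacer interval lies within `window` bases of
#' the position; read counts are summed per template; templates with no
#' events are dropped. Equidistant ties break deterministically on the lowest
#' (chrom, start, strand) with a warning.
#'
#' @param templates a `target_templates` data.frame from
#'   [find_genomic_targets()].
#' @param events data.frame with columns `chrom`, `pos` (0-based), and
#'   `read_count` (positive integers).
#' @param window maximum distance in bases from the integration position to
#'   the protospacer interval (default 25).
#' @param provenance label for the resulting table.
#' @return a [site_table()] of supported sites; unassigned events are kept in
#'   the `unassigned` attribute.
#' @export
assign_integrations <- function(templates, events, window = 25L,
                                provenance = "") {
  stopifnot(all(c("chrom", "pos", "read_count") %in% names(events)))
  if (nrow(events) && any(events$read_count < 1))
    stop("integration events must carry positive read counts")
  window <- as.integer(window)
  n_t <- nrow(templates)
  reads <- integer(n_t)
  unassigned <- logical(nrow(events))
  tie_seen <- FALSE
  for (i in seq_len(nrow(events))) {
    same <- which(templates$chrom == events$chrom[i])
    if (!length(same)) { unassigned[i] <- TRUE; next }
    pos <- events$pos[i]
    st <- templates$start[same]
    en <- templates$end[same]
    d <- ifelse(pos < st, st - pos, ifelse(pos >= en, pos - en + 1L, 0L))
    ok <- d <= window
    if (!any(ok)) { unassigned[i] <- TRUE; next }
    cand <- same[ok]
    dmin <- min(d[ok])
    best <- cand[d[ok] == dmin]
    if (length(best) > 1L) {
      tie_seen <- TRUE
      ord <- order(templates$chrom[best], templates$start[best],
                   templates$strand[best])
      best <- best[ord[1]]
    }
    reads[best] <- reads[best] + as.integer(events$read_count[i])
  }
  if (tie_seen)
    warning("equidistant integration event(s): tie broken on lowest ",
            "(chrom, start, strand)")
  keep <- reads > 0L
  out <- as.data.frame(templates)[keep, SITE_TABLE_COLS, drop = FALSE]
  out$read_count <- reads[keep]
  tab <- site_table(out, provenance = provenance)
  attr(tab, "unassigned") <- events[unassigned, , drop = FALSE]
  tab
}

#' PAM-side flank of sites
#'
#' For a 3' PAM (Cas9-like) the PAM flank is `flank3`, with positions 1..10
#' and position 1 adjacent to the spacer. For a 5' PAM (Cas12a-like) it is
#' `flank5`, with positions -10..-1 and -1 adjacent to the spacer.
#'
#' @param sites a `site_table` or `target_templates` data.frame (or any
#'   data.frame with `flank5`/`flank3` columns).
#' @param orientation `"three_prime"` or `"five_prime"`.
#' @return character vector of 10-nt PAM flanks.
#' @export
pam_flank <- function(sites, orientation = c("three_prime", "five_prime")) {
  orientation <- match.arg(orientation)
  if (orientation == "three_prime") sites$flank3 else sites$flank5
}

# Map a PAM position label to an index in the flank string: for three_prime,
# position j is flank3[j]; for five_prime, position -j is flank5[11 - j]
# (position -1 is the last base of flank5, adjacent to the spacer).
pam_position_index <- function(position, orientation) {
  if (orientation == "three_prime") {
    stopifnot(all(position >= 1L))
    as.integer(position)
  } else {
    stopifnot(all(position <= -1L))
    as.integer(11L + position)
  }
}

# Inverse: flank-string index -> reported PAM position.
pam_index_position <- function(index, orientation) {
  if (orientation == "three_prime") as.integer(index)
  else as.integer(index - 11L)
}

# The L consecutive PAM positions scored at a given offset from the spacer:
# offset 1 means the window starts at the spacer-proximal PAM position.
pam_window_slice <- function(flanks, orientation, window_offset, L) {
  w <- nchar(flanks[1])
  if (orientation == "three_prime") {
    stopifnot(window_offset + L - 1L <= w)
    substr(flanks, window_offset, window_offset + L - 1L)
  } else {
    stopifnot(window_offset + L - 1L <= w)
    to <- w - window_offset + 1L
    substr(flanks, to - L + 1L, to)
  }
}
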