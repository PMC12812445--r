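# Iterative seed-extension motif enrichment over the PAM window: the edited
# value statistic, the per-window chi-square test against genomic background
# counts, and the stepwise extension that produces the motif table.

#' Edited values for a set of motifs
#'
#' The edited value of a motif blends site-level and read-level cleavage
#' evidence: the number of edited (captured) genomic sites matching the
#' motif is summed with the motif's read counts linearly scaled into the
#' site-count range, and the blended value is then normalized so that its
#' maximum equals the highest site count in the comparison. The result
#' lives on the site-count scale (a motif supported by reads in exact
#' proportion to its sites keeps its site count as its value; read excess
#' or deficit shifts it), which is what the downstream chi-square against
#' background target counts assumes. Both factors are shared across the
#' motifs compared within one window.
#'
#' @param site_counts integer vector: edited sites matching each motif.
#' @param read_counts numeric vector: summed reads of those sites.
#' @return data.frame with `site_count`, `read_count`, `scaled_reads`
#'   (reads mapped to the site-count range), `value` (normalized blend,
#'   `max(value) == max(site_count)`); the read scale factor and the final
#'   normalization are in the `scale_factor` / `norm_factor` attributes.
#' @export
edited_value <- function(site_counts, read_counts) {
  stopifnot(length(site_counts) == length(read_counts),
            all(site_counts >= 0), all(read_counts >= 0))
  if (max(read_counts) == 0) {
    warning("all read counts are zero; edited values equal site counts")
    scale <- 0
  } else {
    scale <- max(site_counts) / max(read_counts)
  }
  scaled <- read_counts * scale
  raw <- site_counts + scaled
  norm <- if (max(raw) > 0) max(site_counts) / max(raw) else 1
  structure(data.frame(site_count = site_counts, read_count = read_counts,
                       scaled_reads = scaled,
                       value = raw * norm),
            scale_factor = scale, norm_factor = norm)
}

#' Chi-square test of edited values against background within one window
#'
#' Builds the 2 x k contingency table whose first row is the rounded edited
#' value of each motif and whose second row is the motif's genomic
#' background target count, and applies Pearson's chi-square test
#' (two-sided, df = k - 1): enrichment shows up as a shift of the edited
#' composition away from the background composition across the window's
#' motifs. Because edited sites are drawn from the background targets the
#' test is conservative under no enrichment. Motifs whose column total is
#' zero are dropped with a warning; if fewer than two motifs remain the
#' p-value is undefined.
#'
#' @param edited_values numeric vector of edited values (one per motif).
#' @param background_counts integer vector of genomic background target
#'   counts per motif.
#' @return list with `chi2`, `p_value`, `df`, `table` (the contingency
#'   matrix used), `dropped` (indices of dropped motifs).
#' @export
window_chi_square <- function(edited_values, background_counts) {
  stopifnot(length(edited_values) >= 2,
            length(edited_values) == length(background_counts),
            all(background_counts >= 0))
  e <- round_half_up(edited_values, digits = 0)
  M <- rbind(edited = e, background = background_counts)
  drop <- which(colSums(M) == 0)
  if (length(drop)) {
    warning(length(drop), " motif(s) dropped from chi-square table ",
            "(zero expected counts)")
    M <- M[, -drop, drop = FALSE]
  }
  if (ncol(M) < 2 || any(rowSums(M) == 0))
    return(list(chi2 = NA_real_, p_value = NA_real_, df = NA_integer_,
                table = M, dropped = drop))
  ct <- suppressWarnings(stats::chisq.test(M, correct = FALSE))
  list(chi2 = unname(ct$statistic), p_value = unname(ct$p.value),
       df = unname(ct$parameter), table = M, dropped = drop)
}

#' Percent of genomic targets edited
#'
#' @param edited_sites number of edited sites matching a motif.
#' @param total_sites number of genomic background targets matching it.
#' @return percentage to one decimal place (half away from zero), e.g.
#'   `percent_edited(1103, 1681)` is 65.6.
#' @export
percent_edited <- function(edited_sites, total_sites) {
  stopifnot(all(edited_sites >= 0))
  if (any(total_sites == 0)) stop("total_sites must be positive")
  if (any(edited_sites > total_sites))
    stop("edited_sites cannot exceed total_sites")
  round_half_up(100 * edited_sites / total_sites, digits = 1)
}

# logical row-match of a char matrix against a motif (columns + bases)
motif_match <- function(M, cols, bases) {
  hit <- rep(TRUE, nrow(M))
  for (j in seq_along(cols))
    hit <- hit & M[, cols[j]] == bases[j]
  hit
}

# Evaluate one window: the four candidate motifs extend a shared parent
# match mask by one column, so each candidate is parent-mask AND base-at-col.
# Per-motif edited sites/reads/background, edited values, window chi-square.
eval_window <- function(E, reads, B, col, mask_e, mask_b) {
  s <- integer(4L); r <- numeric(4L); bg <- integer(4L)
  masks_e <- masks_b <- vector("list", 4L)
  for (i in seq_along(DNA_BASES)) {
    me <- mask_e & E[, col] == DNA_BASES[i]
    mb <- mask_b & B[, col] == DNA_BASES[i]
    s[i] <- sum(me); r[i] <- sum(reads[me]); bg[i] <- sum(mb)
    masks_e[[i]] <- me; masks_b[[i]] <- mb
  }
  ev <- suppressWarnings(edited_value(s, r))
  wc <- suppressWarnings(window_chi_square(ev$value, bg))
  list(site_counts = s, read_sums = r, background = bg,
       values = ev$value, chi2 = wc$chi2, p_value = wc$p_value, df = wc$df,
       masks_e = masks_e, masks_b = masks_b)
}

# Pick the reported motif within a window: highest percent edited among
# motifs with background > 0; ties broken by higher edited value, then
# lexicographic motif string.
best_in_window <- function(win, motif_strings) {
  pct <- ifelse(win$background > 0,
                100 * win$site_counts / win$background, -Inf)
  ord <- order(-pct, -win$values, motif_strings)
  ord[1]
}

#' Seed-extension PAM motif table
#'
#' The iterative seed-extension procedure over the PAM window:
#' \enumerate{
#'   \item For every PAM position, compare the four single-base motifs'
#'     edited values against the genomic background counts with a chi-square
#'     test; the position with the smallest p-value seeds the motif.
#'   \item Extend the current motif by one base toward the 5' end or one
#'     base toward the 3' end; each side's four candidate motifs form a new
#'     window comparison, and the more significant side's best motif is
#'     recorded and used for the next round.
#'   \item Repeat until both ends of the PAM window are reached, recording
#'     every step.
#'   \item Report the retained trace: steps that are significant at the
#'     Bonferroni-corrected level and whose percent of genomic targets
#'     edited strictly increases from step to step.
#' }
#' Edited sites include both perfect-match and mismatch sites by default.
#'
#' @param sites a `site_table` of captured (edited) sites.
#' @param targets background `target_templates` (all candidate genomic
#'   targets of the spacer); per-motif background counts are the number of
#'   templates whose PAM flank matches the motif.
#' @param orientation `"three_prime"` or `"five_prime"`.
#' @param pam_window number of PAM positions scanned (default 10).
#' @param alpha significance floor for the retained list (default 0.01),
#'   Bonferroni-corrected by the number of candidate motifs per round.
#' @param perfect_only restrict edited sites to perfect-match sites.
#' @return a `genomepam_table`: list with `steps` (the full trace, one row
#'   per step), `windows` (per-step candidate sub-tables), `retained`
#'   (the filtered trace), `alpha`, `orientation`.
#' @export
seed_extend <- function(sites, targets,
                        orientation = c("three_prime", "five_prime"),
                        pam_window = 10L, alpha = 0.01,
                        perfect_only = FALSE) {
  orientation <- match.arg(orientation)
  W <- as.integer(pam_window)
  if (perfect_only) sites <- sites[sites$match_class == "perfect", , drop = FALSE]
  if (!nrow(sites)) stop("no edited sites")
  if (!nrow(targets)) stop("no background targets")
  E <- seq_matrix(pam_flank(sites, orientation))
  B <- seq_matrix(pam_flank(targets, orientation))
  stopifnot(ncol(E) >= W, ncol(B) >= W)
  E <- E[, seq_len(W), drop = FALSE]
  B <- B[, seq_len(W), drop = FALSE]
  reads <- as.numeric(sites$read_count)

  steps <- list()
  windows <- list()
  record <- function(win, cols, bases_list, n_candidates, side) {
    i <- best_in_window(win, vapply(bases_list, paste, "", collapse = ""))
    motif <- paste(bases_list[[i]], collapse = "")
    pos <- pam_index_position(cols, orientation)
    pct <- if (win$background[i] > 0)
      round_half_up(100 * win$site_counts[i] / win$background[i], 1)
    else NA_real_
    k <- length(steps) + 1L
    steps[[k]] <<- data.frame(
      step_index = k, motif = motif,
      positions = paste(pos, collapse = ","),
      pos_lo = min(pos), pos_hi = max(pos),
      edited_sites = win$site_counts[i],
      total_sites = win$background[i],
      percent_edited = pct,
      edited_value = win$values[i],
      chi2 = win$chi2, p_value = win$p_value,
      n_candidates = n_candidates,
      significant = !is.na(win$p_value) &
        win$p_value <= alpha / n_candidates,
      side = side, stringsAsFactors = FALSE)
    windows[[k]] <<- data.frame(
      motif = vapply(bases_list, paste, "", collapse = ""),
      positions = paste(pos, collapse = ","),
      edited_sites = win$site_counts,
      total_sites = win$background,
      read_sum = win$read_sums,
      edited_value = win$values, stringsAsFactors = FALSE)
    i
  }

  # Step 1: scan every position x base.
  all_e <- rep(TRUE, nrow(E))
  all_b <- rep(TRUE, nrow(B))
  base_list1 <- as.list(DNA_BASES)
  pos_eval <- lapply(seq_len(W), function(p)
    eval_window(E, reads, B, p, all_e, all_b))
  pvals <- vapply(pos_eval, function(w)
    ifelse(is.na(w$p_value), Inf, w$p_value), numeric(1))
  best_pct <- vapply(pos_eval, function(w) {
    pct <- ifelse(w$background > 0, 100 * w$site_counts / w$background, -Inf)
    max(pct)
  }, numeric(1))
  seed_pos <- order(pvals, -best_pct)[1]
  win <- pos_eval[[seed_pos]]
  i <- record(win, seed_pos, base_list1, n_candidates = 4L * W, side = "seed")
  cur_cols <- seed_pos
  cur_bases <- DNA_BASES[i]
  mask_e <- win$masks_e[[i]]
  mask_b <- win$masks_b[[i]]

  # Extension rounds: grow one base at a time toward either end.
  lo <- seed_pos; hi <- seed_pos
  while (lo > 1L || hi < W) {
    cand <- list()
    if (lo > 1L) {
      cand$five <- list(cols = c(lo - 1L, cur_cols),
                        bases = lapply(DNA_BASES, function(b) c(b, cur_bases)),
                        win = eval_window(E, reads, B, lo - 1L, mask_e, mask_b))
    }
    if (hi < W) {
      cand$three <- list(cols = c(cur_cols, hi + 1L),
                         bases = lapply(DNA_BASES, function(b) c(cur_bases, b)),
                         win = eval_window(E, reads, B, hi + 1L, mask_e, mask_b))
    }
    n_cand <- 4L * length(cand)
    pv <- vapply(cand, function(x)
      ifelse(is.na(x$win$p_value), Inf, x$win$p_value), numeric(1))
    bp <- vapply(cand, function(x) {
      pct <- ifelse(x$win$background > 0,
                    100 * x$win$site_counts / x$win$background, -Inf)
      max(pct)
    }, numeric(1))
    # more significant side wins; ties on higher best percent, then 3' side
    pick <- names(cand)[order(pv, -bp,
                              match(names(cand), c("three", "five")))][1]
    ch <- cand[[pick]]
    i <- record(ch$win, ch$cols, ch$bases, n_candidates = n_cand,
                side = if (pick == "five") "5p" else "3p")
    cur_cols <- ch$cols
    cur_bases <- ch$bases[[i]]
    mask_e <- ch$win$masks_e[[i]]
    mask_b <- ch$win$masks_b[[i]]
    if (pick == "five") lo <- lo - 1L else hi <- hi + 1L
  }

  trace <- do.call(rbind, steps)
  retained <- trace[0, , drop = FALSE]
  last_pct <- -Inf
  for (r in seq_len(nrow(trace))) {
    if (isTRUE(trace$significant[r]) &&
        !is.na(trace$percent_edited[r]) &&
        trace$percent_edited[r] > last_pct) {
      retained <- rbind(retained, trace[r, , drop = FALSE])
      last_pct <- trace$percent_edited[r]
    }
  }
  structure(list(steps = trace, windows = windows, retained = retained,
                 alpha = alpha, orientation = orientation,
                 pam_window = W, n_sites = nrow(sites),
                 n_targets = nrow(targets)),
            class = "genomepam_table")
}

#' @export
print.genomepam_table <- function(x, ...) {
  cat("Seed-extension PAM motif table (", x$orientation, " PAM, ",
      x$n_sites, " edited sites / ", x$n_targets,
      " background targets)\n", sep = "")
  cat("Retained motifs:\n")
  if (nrow(x$retained)) {
    df <- x$retained[, c("step_index", "motif", "positions", "edited_sites",
                         "total_sites", "percent_edited", "p_value")]
    print(df, row.names = FALSE)
  } else {
    cat("  (none significant at alpha = ", x$alpha, ")\n", sep = "")
  }
  invisible(x)
}

#' Serialize a motif table to JSON
#'
#' @param x a `genomepam_table`.
#' @param path output path.
#' @param meta optional named list of metadata (version, command, seed)
#'   stored alongside the trace.
#' @return `path`, invisibly.
#' @export
write_genomepam_table <- function(x, path, meta = NULL) {
  stopifnot(inherits(x, "genomepam_table"))
  payload <- list(
    meta = meta,
    alpha = x$alpha, orientation = x$orientation,
    pam_window = x$pam_window,
    n_sites = x$n_sites, n_targets = x$n_targets,
    steps = x$steps, retained = x$retained)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
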