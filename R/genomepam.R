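# The central fit: estimate a nuclease's PAM preference from a cleavage
# site table and the background set of candidate genomic targets.

#' Fit a PAM preference profile
#'
#' Runs the full characterization on one experiment: read-weighted position
#' frequency matrices (overall and stratified by perfect-match vs mismatch
#' sites), the PAM cleavage value (PCV) table with its 4-base heat-map grid,
#' and the iterative seed-extension motif table, all against the supplied
#' background of candidate genomic targets.
#'
#' @param sites a [site_table()] of captured cleavage sites.
#' @param targets background `target_templates` from
#'   [find_genomic_targets()] (or [sim_templates()] for simulated data).
#' @param orientation `"three_prime"` (Cas9-like) or `"five_prime"`
#'   (Cas12a-like).
#' @param pam_len PAM length scored by the PCV table (default 4).
#' @param window_offset first scored PAM position, counted from the spacer
#'   (default 1).
#' @param pam_window number of PAM positions scanned by the motif table
#'   (default 10).
#' @param alpha significance floor of the motif table (default 0.01,
#'   Bonferroni-corrected per round).
#' @param weight_mode `"reads"` or `"sites"` weighting for PFM and PCV.
#' @return a `genomepam` object: list with elements `pfm` (list of
#'   `weighted_pfm` by stratum), `pcv` (a `pcv_table`), `heatmap`
#'   (16 x 16 relative-PCV grid when `pam_len == 4`), `table` (a
#'   `genomepam_table`), `summary_counts`, `orientation`, `call`.
#' @seealso [print.genomepam()], [summary.genomepam()],
#'   [coef.genomepam()], [plot.genomepam()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, n_perfect_targets = 800,
#'                   n_mismatch_targets = 200)
#' truth <- sim_truth(cfg)
#' sites <- sim_capture(truth, cfg)
#' fit <- genomepam(sites, sim_templates(truth))
#' fit
genomepam <- function(sites, targets,
                      orientation = c("three_prime", "five_prime"),
                      pam_len = 4L, window_offset = 1L,
                      pam_window = 10L, alpha = 0.01,
                      weight_mode = c("reads", "sites")) {
  orientation <- match.arg(orientation)
  weight_mode <- match.arg(weight_mode)
  if (!nrow(sites)) stop("site table is empty")
  pfm <- list(all = weighted_pfm(sites, orientation, "all", weight_mode))
  for (st in c("perfect", "mismatch"))
    if (any(sites$match_class == st))
      pfm[[st]] <- weighted_pfm(sites, orientation, st, weight_mode)
  bg_flanks <- pam_flank(targets, orientation)
  pcv <- pcv_table(sites, bg_flanks, L = pam_len, orientation = orientation,
                   window_offset = window_offset, weight_mode = weight_mode)
  hm <- if (pam_len == 4L) heatmap_matrix(pcv) else NULL
  tab <- seed_extend(sites, targets, orientation = orientation,
                     pam_window = pam_window, alpha = alpha)
  structure(list(
    pfm = pfm, pcv = pcv, heatmap = hm, table = tab,
    orientation = orientation, pam_len = as.integer(pam_len),
    alpha = alpha, weight_mode = weight_mode,
    summary_counts = c(
      n_sites = nrow(sites),
      n_perfect = sum(sites$match_class == "perfect"),
      n_mismatch = sum(sites$match_class == "mismatch"),
      total_reads = sum(sites$read_count),
      n_targets = nrow(targets)),
    provenance = attr(sites, "provenance") %||% "",
    call = match.call()),
    class = "genomepam")
}

#' @export
print.genomepam <- function(x, ...) {
  sc <- x$summary_counts
  cat("PAM preference fit (", x$orientation, " PAM)\n", sep = "")
  cat(sprintf("  %d sites (%d perfect / %d mismatch), %s reads, %d background targets\n",
              sc["n_sites"], sc["n_perfect"], sc["n_mismatch"],
              format(sc["total_reads"], big.mark = ","), sc["n_targets"]))
  ret <- x$table$retained
  if (nrow(ret)) {
    last <- ret[nrow(ret), ]
    cat(sprintf("  Top motif: %s at position(s) %s (%.1f%% of %d targets edited, p = %.3g)\n",
                last$motif, last$positions, last$percent_edited,
                last$total_sites, last$p_value))
  } else {
    cat("  No motif retained at alpha =", x$alpha, "\n")
  }
  invisible(x)
}

#' Summarize a PAM preference fit
#'
#' @param object a `genomepam` fit.
#' @param n_top number of top-PCV PAMs to display.
#' @param ... unused.
#' @return a `summary.genomepam` list (printed with its own method).
#' @export
summary.genomepam <- function(object, n_top = 8L, ...) {
  pcv <- object$pcv
  ok <- !pcv$undefined & !is.na(pcv$pcv)
  top <- pcv[ok, ][order(-pcv$pcv[ok]), ][seq_len(min(n_top, sum(ok))), ]
  structure(list(counts = object$summary_counts,
                 orientation = object$orientation,
                 top_pams = top,
                 retained = object$table$retained,
                 alpha = object$alpha),
            class = "summary.genomepam")
}

#' @export
print.summary.genomepam <- function(x, ...) {
  cat("PAM preference summary (", x$orientation, " PAM)\n", sep = "")
  print(x$counts)
  cat("\nTop PAMs by PCV:\n")
  print(x$top_pams[, c("pam", "captured_fraction", "background_fraction",
                       "pcv", "relative_pcv")], row.names = FALSE, digits = 3)
  cat("\nRetained seed-extension motifs:\n")
  if (nrow(x$retained))
    print(x$retained[, c("step_index", "motif", "positions", "edited_sites",
                         "total_sites", "percent_edited", "p_value")],
          row.names = FALSE, digits = 3)
  else cat("  (none at alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' Relative PCV coefficients of a fit
#'
#' @param object a `genomepam` fit.
#' @param ... unused.
#' @return named numeric vector of relative PCV (log2, top PAM = 0) over
#'   defined PAMs.
#' @export
coef.genomepam <- function(object, ...) {
  pcv <- object$pcv
  ok <- !pcv$undefined
  stats::setNames(pcv$relative_pcv[ok], pcv$pam[ok])
}

#' Plot a PAM preference fit
#'
#' Two base-graphics panels: per-position stacked base frequencies of the
#' read-weighted PFM (information-content scaled), and the 4-base relative
#' PCV heat map when available.
#'
#' @param x a `genomepam` fit.
#' @param which `"pfm"`, `"heatmap"`, or `"both"`.
#' @param ... passed to [graphics::image()] for the heat map.
#' @return `x`, invisibly.
#' @export
plot.genomepam <- function(x, which = c("both", "pfm", "heatmap"), ...) {
  which <- match.arg(which)
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  panels <- if (which == "both" && !is.null(x$heatmap)) 2L else 1L
  graphics::par(mfrow = c(1, panels), mar = c(4, 4, 3, 1))
  if (which %in% c("both", "pfm")) {
    pfm <- x$pfm$all$matrix
    ic <- apply(pfm, 2, function(p) {
      p2 <- p[p > 0]
      2 + sum(p2 * log2(p2))
    })
    h <- sweep(pfm, 2, ic, `*`)
    graphics::barplot(h, col = c(A = "#109648", C = "#255C99",
                                 G = "#F7B32B", T = "#D62839"),
                      border = NA, ylim = c(0, 2),
                      xlab = "PAM position", ylab = "bits",
                      main = "PAM base preference (read-weighted)")
    graphics::legend("topright", legend = DNA_BASES, bty = "n",
                     fill = c("#109648", "#255C99", "#F7B32B", "#D62839"))
  }
  if (which %in% c("both", "heatmap") && !is.null(x$heatmap)) {
    m <- x$heatmap
    m[!is.finite(m)] <- NA
    graphics::image(seq_len(ncol(m)), seq_len(nrow(m)),
                    t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                    axes = FALSE, xlab = "positions 3-4",
                    ylab = "positions 1-2",
                    main = "Relative PCV (log2)", ...)
    graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m),
                   las = 2, cex.axis = 0.6)
    graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                   las = 1, cex.axis = 0.6)
  }
  invisible(x)
}
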