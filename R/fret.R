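# De-quenching (acceptor photobleaching) FRET efficiency per cell and
# two-group comparison between receptor variants.

#' Per-cell de-quenching FRET efficiency
#'
#' `E = (DQ - Q) / DQ`, where `Q` is the donor intensity while the acceptor
#' is intact (quenched) and `DQ` the donor intensity after acceptor
#' photobleaching (de-quenched). Scale-invariant: multiplying both
#' intensities by the same positive constant leaves E unchanged. Cells with
#' `Q > DQ` (photobleach failure) return a negative efficiency and are
#' flagged by the summary/comparison functions rather than dropped.
#'
#' @param Q Quenched donor intensity (a.u.), >= 0. Vectorised.
#' @param DQ De-quenched donor intensity (a.u.), must be > 0 after any
#'   background subtraction.
#' @param background Optional per-cell background intensity subtracted from
#'   both `Q` and `DQ` before forming the ratio (default 0: background
#'   correction is assumed done upstream).
#' @return Efficiency fraction(s), same length as the inputs.
#' @examples
#' fret_efficiency(Q = 80, DQ = 100)   # 0.20
#' @export
fret_efficiency <- function(Q, DQ, background = 0) {
  Qc <- Q - background
  DQc <- DQ - background
  if (any(!is.finite(DQc)) || any(DQc <= 0)) {
    stop("`DQ` must be positive (after background subtraction)")
  }
  if (any(Qc < 0)) stop("`Q` must be non-negative (after background subtraction)")
  (DQc - Qc) / DQc
}

#' Summarise a group of FRET cells
#'
#' @param cells data.frame with columns `Q`, `DQ` (optionally `background`,
#'   `group`, `cell_id`), e.g. from [simulate_fret_cells()] or
#'   [read_fret_cells()].
#' @param group Group label; defaults to the table's `group` column.
#' @return An object of class `fret_group_summary`: `group`, `n_cells`,
#'   `mean_E`, `sem_E`, `median_E`, `n_flagged` (cells with E <= 0),
#'   `efficiency` (the per-cell values).
#' @export
summarize_fret_group <- function(cells, group = NULL) {
  stopifnot(is.data.frame(cells), all(c("Q", "DQ") %in% names(cells)))
  if (nrow(cells) < 2) stop("need at least 2 cells for a group summary (SEM)")
  bg <- if ("background" %in% names(cells)) cells$background else 0
  E <- fret_efficiency(cells$Q, cells$DQ, background = bg)
  if (is.null(group)) {
    group <- if ("group" %in% names(cells)) as.character(cells$group[1]) else ""
  }
  structure(list(group = group, n_cells = nrow(cells),
                 mean_E = mean(E), sem_E = stats::sd(E) / sqrt(length(E)),
                 median_E = stats::median(E), n_flagged = sum(E <= 0),
                 efficiency = E),
            class = "fret_group_summary")
}

#' @export
print.fret_group_summary <- function(x, ...) {
  cat(sprintf("FRET group %s: n = %d, mean E = %.3f (SEM %.3f), median E = %.3f",
              x$group, x$n_cells, x$mean_E, x$sem_E, x$median_E))
  if (x$n_flagged > 0) cat(sprintf("  [%d cell(s) with E <= 0 flagged]", x$n_flagged))
  cat("\n")
  invisible(x)
}

#' Compare FRET efficiency between two groups of cells
#'
#' Reports the fold change of group means (`a` over `b`) and a two-sided
#' two-sample test on the per-cell efficiencies: Welch's t-test by default,
#' or the Mann-Whitney (Wilcoxon rank-sum) test. With fewer than 3 cells in
#' a group, or zero variance in both, the comparison falls back to the rank
#' test with a warning.
#'
#' @param a,b data.frames of cells (columns `Q`, `DQ`, optional
#'   `background`).
#' @param test `"welch"` (default) or `"mw"`.
#' @param drop_nonpositive If `TRUE`, cells with E <= 0 are excluded before
#'   testing (they are only flagged otherwise).
#' @return List with `fold` (ratio of mean efficiencies), `statistic`, `p`,
#'   `test`, and the two [summarize_fret_group()] summaries.
#' @examples
#' a <- simulate_fret_cells(0.20, group = "232I", seed = 1)
#' b <- simulate_fret_cells(0.40, group = "232T", seed = 2)
#' compare_fret_groups(b, a)$fold   # about 2
#' @export
compare_fret_groups <- function(a, b, test = c("welch", "mw"),
                                drop_nonpositive = FALSE) {
  test <- match.arg(test)
  sa <- summarize_fret_group(a)
  sb <- summarize_fret_group(b)
  Ea <- sa$efficiency
  Eb <- sb$efficiency
  if (drop_nonpositive) {
    Ea <- Ea[Ea > 0]
    Eb <- Eb[Eb > 0]
  }
  degenerate <- (length(Ea) < 3 || length(Eb) < 3) &&
    (stats::sd(Ea) == 0 || stats::sd(Eb) == 0)
  if (test == "welch" && degenerate) {
    warning("degenerate variance with n < 3; falling back to the rank test")
    test <- "mw"
  }
  if (test == "welch") {
    ht <- stats::t.test(Ea, Eb)
  } else {
    ht <- stats::wilcox.test(Ea, Eb, exact = FALSE)
  }
  list(fold = mean(Ea) / mean(Eb), statistic = unname(ht$statistic),
       p = ht$p.value, test = test, summary_a = sa, summary_b = sb)
}
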