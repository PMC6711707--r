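# Recessive-model case-control statistics on genotype count tables,
# including a parser for published "TT+TC (p1)/CC (p2)" count rows.

#' Recessive-model 2x2 count table
#'
#' Cases and controls split by homozygous minor genotype (CC) versus all
#' other genotypes (TT + TC).
#'
#' @param cases_cc,cases_other,controls_cc,controls_other Non-negative
#'   integer counts.
#' @param label Subphenotype name.
#' @return An object of class `recessive_table`.
#' @export
recessive_table <- function(cases_cc, cases_other, controls_cc,
                            controls_other, label = "") {
  counts <- c(cases_cc, cases_other, controls_cc, controls_other)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("all counts must be non-negative")
  }
  structure(list(cases_cc = cases_cc, cases_other = cases_other,
                 controls_cc = controls_cc, controls_other = controls_other,
                 label = label),
            class = "recessive_table")
}

#' @export
print.recessive_table <- function(x, ...) {
  cat(sprintf("Recessive 2x2 table%s\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  m <- matrix(c(x$cases_cc, x$cases_other, x$controls_cc, x$controls_other),
              2, 2, byrow = TRUE,
              dimnames = list(c("cases", "controls"), c("CC", "TT+TC")))
  print(m)
  invisible(x)
}

# Round half up to `digits` decimals (matches how published percentages are
# displayed; base round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Parse a published genotype-count row
#'
#' Parses the row dialect `"A+B (p1)/C (p2)"`, where `A`, `B`, `C` are the
#' TT, TC and CC counts and `p1`, `p2` the printed percentages of TT+TC and
#' CC. The recomputed percentages must round (half up, 1 decimal) to the
#' printed ones within 0.05, otherwise a validation error names the row.
#'
#' @param text Row string, e.g. `"376+286 (96.2)/26 (3.8)"`.
#' @return List with `tt`, `tc`, `cc`, `pct_other`, `pct_cc`.
#' @examples
#' parse_genotype_row("376+286 (96.2)/26 (3.8)")
#' @export
parse_genotype_row <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  pat <- "^\\s*(\\d+)\\+(\\d+)\\s*\\(([0-9.]+)\\)\\s*/\\s*(\\d+)\\s*\\(([0-9.]+)\\)\\s*$"
  m <- regmatches(text, regexec(pat, text))[[1]]
  if (length(m) != 6) stop("malformed genotype row: ", sQuote(text))
  tt <- as.integer(m[2]); tc <- as.integer(m[3]); cc <- as.integer(m[5])
  pct_other <- as.numeric(m[4]); pct_cc <- as.numeric(m[6])
  total <- tt + tc + cc
  if (total == 0) stop("genotype row with zero total: ", sQuote(text))
  chk_other <- round_half_up(100 * (tt + tc) / total, 1)
  chk_cc <- round_half_up(100 * cc / total, 1)
  if (abs(chk_other - pct_other) > 0.05 || abs(chk_cc - pct_cc) > 0.05) {
    stop(sprintf(
      "percentage mismatch in row %s: counts give %.1f/%.1f, printed %.1f/%.1f",
      sQuote(text), chk_other, chk_cc, pct_other, pct_cc))
  }
  list(tt = tt, tc = tc, cc = cc, pct_other = pct_other, pct_cc = pct_cc)
}

#' CC genotype frequency as a display percentage
#'
#' `100 * cc / (tt + tc + cc)`, rounded half up to 1 decimal for display;
#' the full-precision value is kept in the `"exact"` attribute.
#'
#' @param tt,tc,cc Genotype counts (total > 0).
#' @return Percentage rounded to 1 decimal, with attribute `exact`.
#' @examples
#' cc_frequency(376, 286, 26)   # 3.8
#' @export
cc_frequency <- function(tt, tc, cc) {
  total <- tt + tc + cc
  if (total <= 0) stop("zero total count")
  exact <- 100 * cc / total
  structure(round_half_up(exact, 1), exact = exact)
}

#' Pearson chi-square test on a recessive 2x2 table
#'
#' `sum((O - E)^2 / E)` over the four cells, no continuity correction by
#' default; the p-value comes from the chi-square distribution with 1
#' degree of freedom.
#'
#' @param t A [recessive_table()].
#' @param correct Apply Yates' continuity correction (default `FALSE`).
#' @return List with `chi2` and `p`.
#' @examples
#' pearson_chi2(recessive_table(50, 661, 26, 662))
#' @export
pearson_chi2 <- function(t, correct = FALSE) {
  stopifnot(inherits(t, "recessive_table"))
  O <- matrix(c(t$cases_cc, t$cases_other, t$controls_cc, t$controls_other),
              2, 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  if (any(E == 0)) stop("zero expected cell; chi-square undefined")
  d <- abs(O - E)
  if (correct) d <- pmax(d - 0.5, 0)
  chi2 <- sum(d^2 / E)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Crude recessive odds ratio with Woolf 95% confidence interval
#'
#' `OR = (cases_cc * controls_other) / (cases_other * controls_cc)`, with
#' `CI = exp(log(OR) +/- z * sqrt(sum(1/cell)))`. When any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to every cell (flagged in the
#' result). The Pearson chi-square (on the uncorrected counts) and its
#' p-value are included so the result carries the full association record.
#' Note these are crude (unadjusted) statistics; covariate-adjusted
#' estimates from individual-level data are out of scope.
#'
#' @param t A [recessive_table()]; both case and control margins must be
#'   positive.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `association_result`: `odds_ratio`, `ci_low`,
#'   `ci_high`, `chi2`, `p`, `correction` (`"none"` or `"haldane"`),
#'   `label`.
#' @examples
#' crude_odds_ratio(recessive_table(50, 661, 26, 662))
#' @export
crude_odds_ratio <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "recessive_table"))
  if (t$cases_cc + t$cases_other == 0 || t$controls_cc + t$controls_other == 0) {
    stop("zero margin: need both cases and controls")
  }
  cells <- c(t$cases_cc, t$cases_other, t$controls_cc, t$controls_other)
  correction <- "none"
  if (any(cells == 0)) {
    cells <- cells + 0.5
    correction <- "haldane"
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(sum(1 / cells))
  chi <- tryCatch(pearson_chi2(t), error = function(e) list(chi2 = NA_real_, p = NA_real_))
  structure(list(odds_ratio = or, ci_low = exp(log(or) - half),
                 ci_high = exp(log(or) + half), chi2 = chi$chi2, p = chi$p,
                 correction = correction, label = t$label),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("Recessive-model association%s: OR = %.3f (95%% CI %.3f-%.3f), chi2 = %.3f, p = %.4g%s\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$odds_ratio, x$ci_low, x$ci_high, x$chi2, x$p,
              if (x$correction != "none") " [Haldane +0.5]" else ""))
  invisible(x)
}

#' Batch association analysis of published count rows
#'
#' Parses a common control row and a set of labelled subphenotype rows in
#' the `"A+B (p1)/C (p2)"` dialect, and computes the crude recessive OR,
#' Woolf CI and Pearson chi-square of each subphenotype against the shared
#' controls. Output order follows the input.
#'
#' @param rows Named character vector (or data.frame with columns `label`,
#'   `row_text`) of subphenotype rows.
#' @param control_row Control row string.
#' @return data.frame with columns `label`, `tt`, `tc`, `cc`, `cc_pct`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `chi2`, `p`, `correction`.
#' @examples
#' batch_table1(c("onset<37" = "207+150 (92.7)/28 (7.3)"),
#'              "376+286 (96.2)/26 (3.8)")
#' @export
batch_table1 <- function(rows, control_row) {
  if (is.data.frame(rows)) {
    labels <- rows$label
    rows <- rows$row_text
  } else {
    labels <- names(rows)
    if (is.null(labels)) labels <- sprintf("row%d", seq_along(rows))
  }
  ctrl <- parse_genotype_row(control_row)
  if (length(rows) == 0) {
    return(data.frame(label = character(0), tt = integer(0), tc = integer(0),
                      cc = integer(0), cc_pct = numeric(0),
                      odds_ratio = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), chi2 = numeric(0), p = numeric(0),
                      correction = character(0)))
  }
  out <- lapply(seq_along(rows), function(i) {
    r <- tryCatch(parse_genotype_row(rows[[i]]), error = function(e) {
      stop(sprintf("row %s: %s", labels[i], conditionMessage(e)), call. = FALSE)
    })
    tab <- recessive_table(cases_cc = r$cc, cases_other = r$tt + r$tc,
                           controls_cc = ctrl$cc,
                           controls_other = ctrl$tt + ctrl$tc,
                           label = labels[i])
    a <- crude_odds_ratio(tab)
    data.frame(label = labels[i], tt = r$tt, tc = r$tc, cc = r$cc,
               cc_pct = as.numeric(cc_frequency(r$tt, r$tc, r$cc)),
               odds_ratio = a$odds_ratio, ci_low = a$ci_low,
               ci_high = a$ci_high, chi2 = a$chi2, p = a$p,
               correction = a$correction)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
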