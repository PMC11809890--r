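#' Weighted frequency distribution of a variable
#'
#' @param table a `bivml_table`.
#' @param variable name of the variable to tabulate (an outcome or a
#'   covariate).  Missing covariate values appear as an explicit
#'   `"missing"` level.
#' @return data.frame with columns `level`, `count` (weighted) and `pct`;
#'   percentages sum to 100.
#' @export
weighted_frequency <- function(table, variable) {
  if (!variable %in% names(table)) stop("no such variable: ", variable)
  v <- .desc_factor(table, variable)
  w <- .tab_weight(table)
  cnt <- tapply(w, v, sum, default = 0)
  data.frame(level = names(cnt), count = as.numeric(cnt),
             pct = 100 * as.numeric(cnt) / sum(cnt), row.names = NULL)
}

# factor for descriptive tables: declared level order, NA -> "missing"
.desc_factor <- function(table, variable) {
  sp <- .tab_schema(table)[[variable]]
  v <- as.character(table[[variable]])
  lev <- if (is.null(sp)) sort(unique(stats::na.omit(v))) else sp$levels
  if (anyNA(v)) { v[is.na(v)] <- "missing"; lev <- c(lev, "missing") }
  factor(v, levels = lev)
}

#' Weighted cross-tabulation with a Pearson chi-square test
#'
#' Tabulates weighted counts of a covariate against an outcome and tests
#' independence by the Pearson chi-square on the weighted table, i.e. the
#' design-naive test: weights enter the counts but no survey-design
#' correction (Rao-Scott or similar) is applied.
#'
#' @param table a `bivml_table`.
#' @param covariate row variable name.
#' @param outcome column variable name (typically one of the two outcomes).
#' @return list of class `bivml_crosstab`: `counts` (weighted matrix),
#'   `row_pct`, `statistic`, `df`, `p_value`, plus a `zero_expected` flag.
#' @export
crosstab_chisq <- function(table, covariate, outcome) {
  r <- .desc_factor(table, covariate)
  c_ <- .desc_factor(table, outcome)
  if (nlevels(droplevels(r)) < 2 || nlevels(droplevels(c_)) < 2)
    stop("need at least 2 observed levels in each margin")
  w <- .tab_weight(table)
  counts <- tapply(w, list(r, c_), sum, default = 0)
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  zero_exp <- any(E == 0)
  if (zero_exp) warning("zero expected cell in cross-tab")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(covariate = covariate, outcome = outcome,
                 counts = counts,
                 row_pct = 100 * counts / rowSums(counts),
                 statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value), zero_expected = zero_exp),
            class = "bivml_crosstab")
}

#' @export
print.bivml_crosstab <- function(x, ...) {
  cat(sprintf("%s x %s: X2 = %.4g, df = %d, p = %.4g\n",
              x$covariate, x$outcome, x$statistic, x$df, x$p_value))
  print(round(x$counts, 1))
  invisible(x)
}

#' Weighted joint 2x2 table of the two outcomes
#'
#' The weighted joint distribution of the outcome pair, with cell
#' proportions and both marginals.  Cell `y11` is (outcome1 = 1,
#' outcome2 = 1) -- adequate antenatal care and facility delivery under the
#' default coding -- `y10` is (1,0), `y01` is (0,1), `y00` is (0,0).
#'
#' @param table a `bivml_table` (may be empty; then proportions are `NaN`
#'   and the result carries `degenerate = TRUE`).
#' @return list of class `bivml_joint2x2`: weighted `counts` (y11, y10,
#'   y01, y00), `proportions`, `margins` (`y1` and `y2` totals for level 1
#'   and 0), `total`.
#' @export
joint_outcome_table <- function(table) {
  y1 <- .tab_y1(table); y2 <- .tab_y2(table); w <- .tab_weight(table)
  cnt <- c(y11 = sum(w[y1 == 1 & y2 == 1]), y10 = sum(w[y1 == 1 & y2 == 0]),
           y01 = sum(w[y1 == 0 & y2 == 1]), y00 = sum(w[y1 == 0 & y2 == 0]))
  tot <- sum(cnt)
  structure(list(counts = cnt, total = tot,
                 proportions = cnt / tot,
                 margins = list(y1 = c(`1` = cnt[["y11"]] + cnt[["y10"]],
                                       `0` = cnt[["y01"]] + cnt[["y00"]]),
                                y2 = c(`1` = cnt[["y11"]] + cnt[["y01"]],
                                       `0` = cnt[["y10"]] + cnt[["y00"]])),
                 degenerate = tot == 0),
            class = "bivml_joint2x2")
}

#' @export
print.bivml_joint2x2 <- function(x, ...) {
  cat("Weighted joint 2x2 outcome table (total", format(x$total), ")\n")
  m <- matrix(x$counts, 2, 2, byrow = TRUE,
              dimnames = list(outcome1 = c("1", "0"), outcome2 = c("1", "0")))
  print(round(m, 1))
  if (!x$degenerate) {
    or <- contingency_odds_ratio(x)
    cat(sprintf("odds ratio %.3f (95%% CI %.3f, %.3f)\n",
                or$or_hat, or$ci_low, or$ci_high))
  } else cat("empty table: proportions undefined\n")
  invisible(x)
}

#' Odds ratio of a joint 2x2 table with a Woolf interval
#'
#' Cross-product odds ratio of the weighted table with the Woolf (log)
#' confidence interval: \eqn{\exp(\log\widehat{OR} \pm z\sqrt{\sum 1/n_{ij}})}.
#'
#' @param t a `bivml_joint2x2` from [joint_outcome_table()], or anything
#'   with a `counts` component naming y11, y10, y01, y00.
#' @param level confidence level (default 0.95).
#' @param continuity if `TRUE`, apply the Haldane-Anscombe 0.5 correction
#'   to every cell when any cell is zero; off by default, in which case a
#'   zero cell is an error naming the cell.
#' @return list of class `bivml_or`: `or_hat`, `ci_low`, `ci_high`, `level`.
#' @export
contingency_odds_ratio <- function(t, level = 0.95, continuity = FALSE) {
  n <- t$counts[c("y11", "y10", "y01", "y00")]
  if (any(n == 0)) {
    if (!continuity)
      stop("zero cell(s): ", paste(names(n)[n == 0], collapse = ", "),
           " (set continuity = TRUE for the Haldane-Anscombe correction)",
           call. = FALSE)
    n <- n + 0.5
  }
  or <- (n[["y11"]] * n[["y00"]]) / (n[["y10"]] * n[["y01"]])
  se <- sqrt(sum(1 / n))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(or_hat = or, ci_low = or * exp(-z * se),
                 ci_high = or * exp(z * se), level = level),
            class = "bivml_or")
}

#' @export
print.bivml_or <- function(x, ...) {
  cat(sprintf("OR %.3f (%.0f%% CI %.3f, %.3f)\n",
              x$or_hat, 100 * x$level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Joint risk profile of a covariate over the four outcome combinations
#'
#' Per covariate level, the weighted counts of the four outcome
#' combinations, with row percentages normalised within each level of
#' outcome 1 (the antenatal-care stratum under the default coding): the
#' two no-contact columns sum to 100 per row, as do the two with-contact
#' columns.
#'
#' @param table a `bivml_table`.
#' @param covariate name of the row variable.
#' @return data.frame with one row per covariate level and count / percent
#'   columns `n00` (neither), `n01` (outcome2 only), `n10` (outcome1 only),
#'   `n11` (both), `pct00`, `pct01` (within outcome1 = 0), `pct10`,
#'   `pct11` (within outcome1 = 1).
#' @export
joint_risk_profile <- function(table, covariate) {
  v <- .desc_factor(table, covariate)
  y1 <- .tab_y1(table); y2 <- .tab_y2(table); w <- .tab_weight(table)
  cell <- function(a, b) as.numeric(
    tapply(w * (y1 == a & y2 == b), v, sum, default = 0))
  n00 <- cell(0, 0); n01 <- cell(0, 1); n10 <- cell(1, 0); n11 <- cell(1, 1)
  no <- n00 + n01; yes <- n10 + n11
  data.frame(level = levels(v),
             n00 = n00, n01 = n01, n10 = n10, n11 = n11,
             pct00 = 100 * n00 / no, pct01 = 100 * n01 / no,
             pct10 = 100 * n10 / yes, pct11 = 100 * n11 / yes,
             row.names = NULL)
}
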