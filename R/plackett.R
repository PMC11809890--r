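#' Joint cell probabilities from margins and a cell odds ratio
#'
#' Given the two marginal success probabilities of a pair of binary variables
#' and the cell (cross-product) odds ratio psi linking them, returns the
#' unique joint distribution on the 2x2 table with those margins and that
#' odds ratio -- the Plackett (global odds-ratio) construction.  psi = 1
#' gives independence; psi -> 0 and psi -> Inf approach the Frechet lower
#' and upper bounds for the (1,1) cell.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param p1 marginal success probability of the first outcome, in (0,1).
#' @param p2 marginal success probability of the second outcome, in (0,1).
#' @param psi cell odds ratio, strictly positive.
#' @return A data.frame with columns `p11`, `p10`, `p01`, `p00`, one row per
#'   input element.  Rows sum to 1; `p11 + p10` equals `p1` and `p11 + p01`
#'   equals `p2` exactly (the off cells are formed by margin subtraction).
#' @examples
#' plackett_cells(0.5, 0.5, 1)       # independence: all cells 0.25
#' plackett_cells(0.43, 0.525, 5.435)
#' @seealso [cell_odds_ratio()] for the inverse map.
#' @export
plackett_cells <- function(p1, p2, psi) {
  n <- max(length(p1), length(p2), length(psi))
  p1 <- rep_len(p1, n); p2 <- rep_len(p2, n); psi <- rep_len(psi, n)
  if (any(!is.finite(psi)) || any(psi <= 0))
    stop("psi must be finite and > 0", call. = FALSE)
  if (any(p1 <= 0 | p1 >= 1 | p2 <= 0 | p2 >= 1))
    stop("margins must lie strictly inside (0, 1)", call. = FALSE)

  p11 <- .plackett_p11(p1, p2, psi)
  data.frame(p11 = p11, p10 = p1 - p11, p01 = p2 - p11,
             p00 = 1 - p1 - p2 + p11)
}

# p11 solving psi = p11*p00 / (p10*p01) at fixed margins.
# Quadratic in p11: (psi-1) p11^2 - a p11 + psi p1 p2 = 0,
# a = 1 + (p1+p2)(psi-1); the admissible root is the "-" branch.
# Near psi = 1 the "-" branch cancels catastrophically, so below the
# switching threshold the rationalised limit-stable form is used
# (see cells_near_independence); for psi >= 1 the rationalised form is
# stable everywhere and is used outright.
.plackett_p11 <- function(p1, p2, psi) {
  a <- 1 + (p1 + p2) * (psi - 1)
  disc <- a * a - 4 * psi * (psi - 1) * p1 * p2
  D <- sqrt(pmax(disc, 0))
  # the "-" root, rationalised to 2 psi p1 p2 / (a + D) wherever a > 0
  # (no subtractive cancellation; exact through psi = 1); the classical
  # form only where a <= 0, where it is the cancellation-free expression
  p11 <- ifelse(abs(psi - 1) < 1e-6 | a > 0,
                .p11_near_independence(p1, p2, psi, a, D),
                (a - D) / (2 * (psi - 1)))
  lo <- pmax(0, p1 + p2 - 1); hi <- pmin(p1, p2)
  bad <- which(p11 < lo | p11 > hi | !is.finite(p11))
  for (i in bad) p11[i] <- .p11_bisect(p1[i], p2[i], psi[i])
  p11
}

# Rationalised root 2 psi p1 p2 / (a + D): continuous through psi = 1,
# where a -> 1, D -> 1, p11 -> p1 p2.
.p11_near_independence <- function(p1, p2, psi, a, D) {
  2 * psi * p1 * p2 / (a + D)
}

# Guarded fallback: monotone bisection of g(p11) = p11*p00 - psi*p10*p01
# on the Frechet interval.  Only reached if floating point pushes the
# closed-form root outside the bounds.
.p11_bisect <- function(p1, p2, psi) {
  lo <- max(0, p1 + p2 - 1); hi <- min(p1, p2)
  g <- function(x) x * (1 - p1 - p2 + x) - psi * (p1 - x) * (p2 - x)
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-16) break
  }
  (lo + hi) / 2
}

#' Limit-stable joint cells near independence
#'
#' Evaluates the same margins-plus-odds-ratio map as [plackett_cells()] by
#' the rationalised root \eqn{2\psi p_1 p_2 / (a + \sqrt{a^2 - 4\psi(\psi-1)p_1p_2})},
#' which is free of the subtractive cancellation the classical quadratic
#' root suffers as \eqn{\psi \to 1}.  [plackett_cells()] dispatches here
#' automatically when `|psi - 1| < 1e-6`; the function is exported so the
#' two branches can be compared directly.
#'
#' @inheritParams plackett_cells
#' @return As [plackett_cells()].
#' @export
cells_near_independence <- function(p1, p2, psi) {
  n <- max(length(p1), length(p2), length(psi))
  p1 <- rep_len(p1, n); p2 <- rep_len(p2, n); psi <- rep_len(psi, n)
  a <- 1 + (p1 + p2) * (psi - 1)
  D <- sqrt(pmax(a * a - 4 * psi * (psi - 1) * p1 * p2, 0))
  p11 <- .p11_near_independence(p1, p2, psi, a, D)
  data.frame(p11 = p11, p10 = p1 - p11, p01 = p2 - p11,
             p00 = 1 - p1 - p2 + p11)
}

#' Cell odds ratio of a 2x2 joint distribution
#'
#' The cross-product ratio \eqn{\psi = p_{11} p_{00} / (p_{10} p_{01})},
#' the association measure inverted by [plackett_cells()].
#'
#' @param cells a data.frame (or one-row list) with components `p11`,
#'   `p10`, `p01`, `p00`, as returned by [plackett_cells()].
#' @return Numeric vector of odds ratios.  A zero off-diagonal cell gives
#'   `Inf` with a warning rather than an error.
#' @export
cell_odds_ratio <- function(cells) {
  num <- cells$p11 * cells$p00
  den <- cells$p10 * cells$p01
  if (any(den == 0 & num > 0))
    warning("zero off-diagonal cell: odds ratio is infinite")
  num / den
}

# Partial derivatives of p11 w.r.t. the margins, from implicit
# differentiation of the rationalised root:
#   dp11/dp1 = (1 - (a - 2 psi p2)/D) / 2   (and symmetrically for p2).
# Continuous at psi = 1 (reduces to p2 resp. p1).  Internal; used by the
# likelihood gradients.
.dp11_dmargins <- function(p1, p2, psi) {
  a <- 1 + (p1 + p2) * (psi - 1)
  D <- sqrt(pmax(a * a - 4 * psi * (psi - 1) * p1 * p2, .Machine$double.xmin))
  list(dp1 = 0.5 * (1 - (a - 2 * psi * p2) / D),
       dp2 = 0.5 * (1 - (a - 2 * psi * p1) / D))
}
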