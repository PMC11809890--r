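#' Parameters of the bivariate two-level logistic model
#'
#' The model has two marginal logistic predictors (one per outcome), a
#' log odds-ratio association `alpha` tying the outcomes together through
#' the Plackett construction, and a cluster-level random intercept whose
#' structure is one of:
#' \describe{
#'   \item{shared}{one normal intercept u per cluster entering both
#'     predictors; `sigma` is its standard deviation.}
#'   \item{independent}{a pair (u1, u2) per cluster, independent normals
#'     with SDs `sigma = c(sigma1, sigma2)`.}
#'   \item{correlated}{a bivariate normal pair with
#'     `sigma = c(sigma1, sigma2, rho)`.}
#' }
#'
#' @param beta1,beta2 coefficient vectors on the log-odds scale, matching
#'   the columns of the design matrices.
#' @param alpha log cell odds ratio (log psi); `alpha = 0` is conditional
#'   independence of the outcomes given the covariates and random effect.
#' @param re_structure random-effect structure, see Details.
#' @param sigma random-effect scale parameter(s); see `re_structure`.
#' @return object of class `bivml_parameters`.
#' @export
bivml_parameters <- function(beta1, beta2, alpha = 0,
                             re_structure = c("shared", "independent",
                                              "correlated"),
                             sigma = 0) {
  re_structure <- match.arg(re_structure)
  need <- switch(re_structure, shared = 1, independent = 2, correlated = 3)
  if (length(sigma) != need)
    stop("sigma must have length ", need, " for structure ", re_structure)
  if (any(sigma[seq_len(min(2, need))] < 0)) stop("sigma must be >= 0")
  if (re_structure == "correlated" && abs(sigma[3]) > 1)
    stop("|rho| must be <= 1")
  structure(list(beta1 = beta1, beta2 = beta2, alpha = alpha,
                 re_structure = re_structure, sigma = sigma),
            class = "bivml_parameters")
}

# random-effect dimension of a structure
.re_dim <- function(params) if (params$re_structure == "shared") 1L else 2L

#' Linear predictors given cluster effects
#'
#' eta1 = X1 beta1 + u1[cluster], eta2 = X2 beta2 + u2[cluster]; the shared
#' structure uses u1 = u2 = u.
#'
#' @param params a [bivml_parameters()] object.
#' @param design a `bivml_design` from [encode_design()].
#' @param u cluster effects: a vector (one per cluster) for the shared
#'   structure, or an n_clusters x 2 matrix otherwise.
#' @return list with numeric vectors `eta1` and `eta2`, one entry per unit.
#' @export
linear_predictors <- function(params, design, u) {
  if (length(params$beta1) != ncol(design$X1) ||
      length(params$beta2) != ncol(design$X2))
    stop("coefficient length does not match design columns")
  nc <- length(design$cluster_levels)
  if (.re_dim(params) == 1L) {
    u <- rep_len(as.numeric(u), nc)
    u1 <- u2 <- u
  } else {
    u <- matrix(u, nrow = nc, ncol = 2)
    u1 <- u[, 1]; u2 <- u[, 2]
  }
  ci <- design$cluster_index
  list(eta1 = unname(drop(design$X1 %*% params$beta1) + u1[ci]),
       eta2 = unname(drop(design$X2 %*% params$beta2) + u2[ci]))
}

#' Log-likelihood of one outcome pair under given joint cells
#'
#' The outcome pair follows a four-cell multinomial; the log-likelihood of
#' a unit is the log of the single cell its pair selects.
#'
#' @param y1,y2 binary outcomes (vectorised).
#' @param cells joint cell probabilities as from [plackett_cells()]
#'   (recycled across units).
#' @return numeric vector of log cell probabilities; a nonpositive selected
#'   cell yields `-Inf` with a warning.
#' @export
unit_loglik <- function(y1, y2, cells) {
  p <- ifelse(y1 == 1,
              ifelse(y2 == 1, cells$p11, cells$p10),
              ifelse(y2 == 1, cells$p01, cells$p00))
  if (any(p <= 0)) warning("nonpositive selected cell: -Inf log-likelihood")
  log(p)
}

# vectorised conditional log-likelihood terms at given linear predictors
.cond_loglik_terms <- function(eta1, eta2, psi, y1, y2) {
  p1 <- stats::plogis(eta1); p2 <- stats::plogis(eta2)
  cells <- plackett_cells(p1, p2, psi)
  unit_loglik(y1, y2, cells)
}

# per-unit d log p_sel / d eta1 and d eta2 (chain rule through the
# Plackett inversion); used by the inner Newton mode search
.cond_dloglik_deta <- function(eta1, eta2, psi, y1, y2) {
  p1 <- stats::plogis(eta1); p2 <- stats::plogis(eta2)
  cells <- plackett_cells(p1, p2, psi)
  d <- .dp11_dmargins(p1, p2, psi)
  sel11 <- y1 == 1 & y2 == 1; sel10 <- y1 == 1 & y2 == 0
  sel01 <- y1 == 0 & y2 == 1
  p_sel <- ifelse(sel11, cells$p11,
                  ifelse(sel10, cells$p10,
                         ifelse(sel01, cells$p01, cells$p00)))
  dp_dp1 <- ifelse(sel11, d$dp1,
                   ifelse(sel10, 1 - d$dp1,
                          ifelse(sel01, -d$dp1, d$dp1 - 1)))
  dp_dp2 <- ifelse(sel11, d$dp2,
                   ifelse(sel10, -d$dp2,
                          ifelse(sel01, 1 - d$dp2, d$dp2 - 1)))
  list(deta1 = dp_dp1 * p1 * (1 - p1) / p_sel,
       deta2 = dp_dp2 * p2 * (1 - p2) / p_sel)
}

# log density and gradient of the random-effect prior at u
# (u: vector for d=1, n x 2 matrix for d=2)
.re_prior <- function(params, u) {
  s <- params$sigma
  if (.re_dim(params) == 1L) {
    list(logd = stats::dnorm(u, 0, s, log = TRUE), grad = -u / s^2)
  } else {
    s1 <- s[1]; s2 <- s[2]
    rho <- if (params$re_structure == "correlated") s[3] else 0
    u <- matrix(u, ncol = 2)
    q <- (u[, 1]^2 / s1^2 - 2 * rho * u[, 1] * u[, 2] / (s1 * s2) +
            u[, 2]^2 / s2^2) / (1 - rho^2)
    logd <- -log(2 * pi) - log(s1 * s2) - 0.5 * log(1 - rho^2) - q / 2
    g1 <- -(u[, 1] / s1^2 - rho * u[, 2] / (s1 * s2)) / (1 - rho^2)
    g2 <- -(u[, 2] / s2^2 - rho * u[, 1] / (s1 * s2)) / (1 - rho^2)
    list(logd = logd, grad = cbind(g1, g2))
  }
}

#' Conditional log-likelihood of one cluster at a given effect value
#'
#' The integrand of the marginal likelihood: the sum over the cluster's
#' units of the joint outcome log-likelihood at the linear predictors
#' implied by `u`, plus the log normal density of `u` under the
#' random-effect distribution.  Unit weights, when enabled, multiply the
#' data terms only (pseudo-likelihood); the prior term is unweighted.
#'
#' @param params a [bivml_parameters()].
#' @param design a `bivml_design`.
#' @param cluster a cluster label (as in `design$cluster_levels`) or index.
#' @param u effect value(s) for this cluster: scalar (shared) or length-2.
#' @param weighted apply the design weights to the data terms.
#' @return scalar log-likelihood contribution.
#' @export
cluster_conditional_loglik <- function(params, design, cluster, u,
                                       weighted = FALSE) {
  j <- if (is.numeric(cluster)) as.integer(cluster)
       else match(as.character(cluster), design$cluster_levels)
  if (is.na(j) || j < 1 || j > length(design$cluster_levels))
    stop("unknown cluster: ", cluster)
  idx <- which(design$cluster_index == j)
  nc <- length(design$cluster_levels)
  if (.re_dim(params) == 1L) {
    U <- rep(0, nc); U[j] <- u
  } else {
    U <- matrix(0, nc, 2); U[j, ] <- u
  }
  eta <- linear_predictors(params, design, U)
  ll <- .cond_loglik_terms(eta$eta1[idx], eta$eta2[idx], exp(params$alpha),
                           design$y1[idx], design$y2[idx])
  w <- if (weighted) design$weight[idx] else rep(1, length(idx))
  prior <- .re_prior(params, if (.re_dim(params) == 1L) u
                     else matrix(u, 1, 2))
  sum(w * ll) + sum(prior$logd)
}
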