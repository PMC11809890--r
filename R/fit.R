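# Quasi-Newton maximisation of the Laplace marginal likelihood, standard
# errors from the observed information, AOR tables and the model ladder.

# pack/unpack the free parameter vector.  Transforms: sigma on the log
# scale, rho through atanh, so the outer optimisation is unconstrained.
.theta_pack <- function(params, fix_alpha, fix_sigma) {
  th <- c(params$beta1, params$beta2)
  if (is.null(fix_alpha)) th <- c(th, params$alpha)
  if (is.null(fix_sigma)) {
    s <- params$sigma
    th <- switch(params$re_structure,
                 shared = c(th, log(max(s, 1e-4))),
                 independent = c(th, log(pmax(s, 1e-4))),
                 correlated = c(th, log(pmax(s[1:2], 1e-4)), atanh(s[3])))
  }
  th
}

.theta_unpack <- function(theta, p1, p2, re_structure, fix_alpha,
                          fix_sigma) {
  beta1 <- theta[seq_len(p1)]
  beta2 <- theta[p1 + seq_len(p2)]
  k <- p1 + p2
  if (is.null(fix_alpha)) { alpha <- theta[k + 1]; k <- k + 1 }
  else alpha <- fix_alpha
  if (is.null(fix_sigma)) {
    sigma <- switch(re_structure,
                    shared = exp(theta[k + 1]),
                    independent = exp(theta[k + 1:2]),
                    correlated = c(exp(theta[k + 1:2]), tanh(theta[k + 3])))
  } else sigma <- fix_sigma
  bivml_parameters(beta1, beta2, alpha, re_structure, sigma)
}

# documented initialisation: separate logistic fits for the betas, the
# crude 2x2 log odds ratio for alpha (0.5 correction if a cell is empty),
# and a between-cluster moment guess for sigma (0.5 if degenerate)
.fit_start <- function(design, re_structure) {
  g1 <- stats::glm.fit(design$X1, design$y1,
                       family = stats::binomial())$coefficients
  g2 <- stats::glm.fit(design$X2, design$y2,
                       family = stats::binomial())$coefficients
  n <- c(sum(design$y1 == 1 & design$y2 == 1),
         sum(design$y1 == 1 & design$y2 == 0),
         sum(design$y1 == 0 & design$y2 == 1),
         sum(design$y1 == 0 & design$y2 == 0))
  if (any(n == 0)) n <- n + 0.5
  alpha0 <- log(n[1] * n[4] / (n[2] * n[3]))
  # between-cluster variance of empirical logits, less the sampling part
  sig0 <- local({
    cl <- design$cluster_index
    m <- as.numeric(table(cl))
    guess <- function(y) {
      p <- as.numeric(tapply(y, cl, mean))
      p <- pmin(pmax(p, 1 / (2 * m)), 1 - 1 / (2 * m))
      v <- stats::var(stats::qlogis(p)) - mean(1 / (m * p * (1 - p)))
      if (!is.finite(v) || v <= 0.01) 0.25 else v
    }
    sqrt(mean(c(guess(design$y1), guess(design$y2))))
  })
  sigma0 <- switch(re_structure, shared = sig0,
                   independent = c(sig0, sig0),
                   correlated = c(sig0, sig0, 0.3))
  bivml_parameters(g1, g2, alpha0, re_structure, sigma0)
}

#' Fit the bivariate two-level logistic model
#'
#' Maximises the Laplace-approximated marginal log-likelihood over the two
#' marginal coefficient vectors, the log odds-ratio association and the
#' random-effect scale(s), by BFGS on the unconstrained parameterisation
#' (log sigma, atanh rho).  Starting values are the separate logistic fits
#' for the betas, the crude 2x2 log odds ratio for alpha, and a
#' between-cluster moment guess for sigma.  Standard errors come from the
#' inverse of a finite-difference Hessian of the marginal log-likelihood
#' at the optimum (Wald inference throughout).
#'
#' @param data a `bivml_table` from [analysis_table()] or [load_table()].
#' @param covariates1,covariates2 covariate names for the two predictors.
#' @param re_structure random-effect structure, see [bivml_parameters()].
#' @param weighted use the sampling weights in the likelihood
#'   (pseudo-likelihood); off by default.
#' @param fix_alpha fix the log association at this value instead of
#'   estimating it (e.g. `0` for conditional independence), or `NULL`.
#' @param fix_sigma fix the random-effect scale(s) (e.g. `0` for a purely
#'   fixed-effect model), or `NULL` to estimate.
#' @param se compute standard errors (skippable for speed in simulations).
#' @param control list: `reltol` (outer BFGS relative tolerance, default
#'   1e-8), `maxit` (default 500).
#' @return object of class `bivml_fit`: `params_hat`, `se` (named, on the
#'   estimation scale), `aor_table`, `association_or`, `icc`, `loglik`,
#'   `aic`, `bic`, `n_units`, `n_clusters`, `convergence`, `vcov`.
#' @export
fit_bivml <- function(data, covariates1 = character(),
                      covariates2 = character(),
                      re_structure = c("shared", "independent",
                                       "correlated"),
                      weighted = FALSE, fix_alpha = NULL, fix_sigma = NULL,
                      se = TRUE, control = list()) {
  re_structure <- match.arg(re_structure)
  design <- encode_design(data, covariates1, covariates2)
  if (length(design$cluster_levels) < 2 && is.null(fix_sigma))
    stop("at least 2 clusters are required for a multilevel fit",
         call. = FALSE)
  fit_bivml_design(design, re_structure, weighted, fix_alpha, fix_sigma,
                   se, control)
}

# core fitter on a prebuilt design (also used by the ladder)
fit_bivml_design <- function(design, re_structure = "shared",
                             weighted = FALSE, fix_alpha = NULL,
                             fix_sigma = NULL, se = TRUE, control = list()) {
  ctl <- utils::modifyList(list(reltol = 1e-8, maxit = 500), control)
  p1 <- ncol(design$X1); p2 <- ncol(design$X2)
  start <- .fit_start(design, re_structure)
  if (!is.null(fix_alpha)) start$alpha <- fix_alpha
  if (!is.null(fix_sigma)) start$sigma <- fix_sigma
  theta0 <- .theta_pack(start, fix_alpha, fix_sigma)

  cache <- new.env(parent = emptyenv())
  negll <- function(theta) {
    par <- .theta_unpack(theta, p1, p2, re_structure, fix_alpha, fix_sigma)
    ll <- tryCatch(
      laplace_marginal_loglik(par, design, weighted,
                              u_start = cache$modes),
      error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    cache$modes <- attr(ll, "modes")
    -as.numeric(ll)
  }

  opt <- stats::optim(theta0, negll, method = "BFGS",
                      control = list(reltol = ctl$reltol,
                                     maxit = ctl$maxit))
  theta_hat <- opt$par
  params_hat <- .theta_unpack(theta_hat, p1, p2, re_structure, fix_alpha,
                              fix_sigma)
  loglik <- -opt$value

  grad <- .num_grad(negll, theta_hat)
  conv <- list(status = if (opt$convergence == 0) "converged"
               else paste0("optim code ", opt$convergence),
               iterations = unname(opt$counts["function"]),
               gradient_norm = max(abs(grad)))
  if (opt$convergence != 0)
    warning("optimiser did not report convergence (code ",
            opt$convergence, ")")

  V <- NULL; se_vec <- rep(NA_real_, length(theta_hat))
  if (se) {
    H <- tryCatch(stats::optimHess(theta_hat, negll), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V) && all(diag(V) > 0)) se_vec <- sqrt(diag(V))
      else {
        V <- NULL
        warning("observed information not positive definite; SEs unavailable")
      }
    }
  }
  names(theta_hat) <- names(se_vec) <- .theta_names(design, re_structure,
                                                   fix_alpha, fix_sigma)

  out <- .assemble_fit(params_hat, theta_hat, se_vec, V, design, loglik,
                       conv, fix_alpha, fix_sigma, weighted)
  out
}

.theta_names <- function(design, re_structure, fix_alpha, fix_sigma) {
  nm <- c(paste0("y1:", colnames(design$X1)),
          paste0("y2:", colnames(design$X2)))
  if (is.null(fix_alpha)) nm <- c(nm, "alpha")
  if (is.null(fix_sigma))
    nm <- c(nm, switch(re_structure, shared = "log_sigma",
                       independent = c("log_sigma1", "log_sigma2"),
                       correlated = c("log_sigma1", "log_sigma2",
                                      "atanh_rho")))
  nm
}

.assemble_fit <- function(params, theta, se_vec, V, design, loglik, conv,
                          fix_alpha, fix_sigma, weighted) {
  p1 <- ncol(design$X1); p2 <- ncol(design$X2)
  z975 <- stats::qnorm(0.975)
  beta <- c(params$beta1, params$beta2)
  se_beta <- se_vec[seq_len(p1 + p2)]
  zstat <- beta / se_beta
  pval <- 2 * stats::pnorm(-abs(zstat))
  aor <- data.frame(
    outcome = c(rep("y1", p1), rep("y2", p2)),
    term = c(colnames(design$X1), colnames(design$X2)),
    beta = beta, se = se_beta,
    aor = exp(beta),
    ci_low = exp(beta - z975 * se_beta),
    ci_high = exp(beta + z975 * se_beta),
    p = pval, sig = !is.na(pval) & pval < 0.05,
    row.names = NULL)

  k <- p1 + p2
  assoc <- NULL
  if (is.null(fix_alpha)) {
    a <- params$alpha; sa <- se_vec[k + 1]; k <- k + 1
    assoc <- list(alpha = a, or = exp(a),
                  ci_low = exp(a - z975 * sa), ci_high = exp(a + z975 * sa),
                  se_alpha = sa,
                  p = 2 * stats::pnorm(-abs(a / sa)))
  } else assoc <- list(alpha = fix_alpha, or = exp(fix_alpha),
                       ci_low = NA, ci_high = NA, se_alpha = NA, p = NA)

  icc_val <- icc_se <- NULL
  c0 <- pi^2 / 3
  if (params$re_structure == "shared") {
    s2 <- params$sigma^2
    icc_val <- icc(s2)
    if (is.null(fix_sigma) && is.finite(se_vec[k + 1]))
      # delta method through t = log sigma: dICC/dt = 2 s2 c /(s2+c)^2
      icc_se <- 2 * s2 * c0 / (s2 + c0)^2 * se_vec[k + 1]
  } else {
    s2 <- params$sigma[1:2]^2
    icc_val <- icc(s2)
    if (is.null(fix_sigma) && all(is.finite(se_vec[k + 1:2])))
      icc_se <- 2 * s2 * c0 / (s2 + c0)^2 * se_vec[k + 1:2]
  }

  p_count <- length(theta)
  ics <- information_criteria(loglik, p_count, length(design$y1),
                              length(design$cluster_levels))
  structure(list(
    params_hat = params, theta = theta, se = se_vec, vcov = V,
    aor_table = aor, association_or = assoc,
    icc = icc_val, icc_se = icc_se, sigma2 = s2,
    loglik = loglik, aic = unname(ics["aic"]), bic = unname(ics["bic"]),
    p_count = p_count,
    n_units = length(design$y1),
    n_clusters = length(design$cluster_levels),
    weighted = weighted, convergence = conv, design = design),
    class = "bivml_fit")
}

#' @export
print.bivml_fit <- function(x, ...) {
  cat("Bivariate two-level logistic fit (",
      x$params_hat$re_structure, " random intercept)\n", sep = "")
  cat(sprintf("  %d units in %d clusters; logLik %.3f, AIC %.2f, BIC %.2f\n",
              x$n_units, x$n_clusters, x$loglik, x$aic, x$bic))
  cat(sprintf("  association OR %.3f (95%% CI %.3f, %.3f)\n",
              x$association_or$or, x$association_or$ci_low,
              x$association_or$ci_high))
  cat("  sigma^2:", format(round(x$sigma2, 4)),
      " ICC:", format(round(x$icc, 4)), "\n")
  cat("  convergence:", x$convergence$status, "\n\n")
  df <- x$aor_table
  df[c("beta", "se", "aor", "ci_low", "ci_high", "p")] <-
    lapply(df[c("beta", "se", "aor", "ci_low", "ci_high", "p")],
           function(v) round(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

# central-difference gradient (for the convergence report)
.num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 0)
}

#' Fit the four-model comparison ladder
#'
#' Fits the null (intercept-only), individual-covariate, community-covariate
#' and full models and compares them by ICC, AIC and BIC, flagging the
#' criterion-minimising model.  A failing member is reported with its error
#' message, not fatal.
#'
#' @param data a `bivml_table`.
#' @param individual_covs,community_covs covariate names at the two levels
#'   (entering both outcomes' predictors).
#' @param ... passed to [fit_bivml()].
#' @return list of class `bivml_ladder`: `table` (one row per model with
#'   icc, loglik, aic, bic, status), `fits`, `best_aic`, `best_bic`.
#' @export
model_ladder <- function(data, individual_covs, community_covs, ...) {
  levels <- list(
    null = character(),
    individual = individual_covs,
    community = community_covs,
    full = c(individual_covs, community_covs))
  fits <- lapply(levels, function(cv)
    tryCatch(fit_bivml(data, cv, cv, ...), error = function(e) e))
  ok <- !vapply(fits, inherits, TRUE, "error")
  row <- function(f, good) {
    if (!good) return(data.frame(icc = NA, loglik = NA, aic = NA, bic = NA,
                                 status = "failed"))
    data.frame(icc = f$icc[1], loglik = f$loglik, aic = f$aic, bic = f$bic,
               status = f$convergence$status)
  }
  tab <- do.call(rbind, Map(row, fits, ok))
  tab <- cbind(model = names(levels), tab)
  rownames(tab) <- NULL
  for (f in fits[!ok]) warning("ladder member failed: ",
                               conditionMessage(f))
  structure(list(table = tab, fits = fits,
                 best_aic = tab$model[which.min(tab$aic)],
                 best_bic = tab$model[which.min(tab$bic)]),
            class = "bivml_ladder")
}

#' @export
print.bivml_ladder <- function(x, ...) {
  tab <- x$table
  tab[c("icc", "loglik", "aic", "bic")] <-
    lapply(tab[c("icc", "loglik", "aic", "bic")],
           function(v) round(v, 3))
  print(tab, row.names = FALSE)
  cat("best by AIC:", x$best_aic, " best by BIC:", x$best_bic, "\n")
  invisible(x)
}
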