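test_that("sigma = 0 collapses the marginal likelihood exactly", {
  tab <- small_table(n = 50, seed = 13)
  d <- encode_design(tab, "grp", "grp")
  par <- bivml_parameters(c(0.2, 0.1, -0.3), c(-0.1, 0, 0.2), 0.4,
                          "shared", 0)
  eta <- linear_predictors(par, d, rep(0, 2))
  cells <- plackett_cells(plogis(eta$eta1), plogis(eta$eta2),
                          exp(par$alpha))
  expect_equal(as.numeric(laplace_marginal_loglik(par, d)),
               sum(unit_loglik(d$y1, d$y2, cells)))
})

test_that("Laplace tracks a dense trapezoid oracle within 2%", {
  # one informative cluster, few units, sigma = 1
  df <- data.frame(y1 = c(1, 1, 0, 1, 0, 1), y2 = c(1, 0, 0, 1, 1, 1),
                   cluster = c(rep("a", 3), rep("b", 3)))
  tab <- analysis_table(df)
  d <- encode_design(tab, character(), character())
  par <- bivml_parameters(0.2, -0.1, 0.7, "shared", 1)
  ll <- as.numeric(laplace_marginal_loglik(par, d))
  oracle <- sum(vapply(c("a", "b"), function(cl) {
    us <- seq(-8, 8, length.out = 10001)
    f <- vapply(us, function(u)
      exp(cluster_conditional_loglik(par, d, cl, u)), 0)
    log(sum((f[-1] + f[-length(f)]) / 2) * diff(us)[1])
  }, 0))
  expect_lt(abs(ll - oracle) / abs(oracle), 0.02)

  # AGQ with 1 node is Laplace; more nodes converge to the oracle
  expect_equal(agq_marginal_loglik(par, d, nodes = 1), ll,
               tolerance = 1e-10)
  expect_equal(agq_marginal_loglik(par, d, nodes = 25), oracle,
               tolerance = 1e-6)
  expect_equal(agq_marginal_loglik(par, d, nodes = 15),
               agq_marginal_loglik(par, d, nodes = 25),
               tolerance = 1e-6)
})

test_that("two-dimensional structures integrate correctly", {
  tab <- small_table(n = 60, seed = 31, n_clusters = 3)
  d <- encode_design(tab, "grp", "grp")
  pari <- bivml_parameters(c(0.2, 0.1, -0.3), c(-0.1, 0, 0.2), 0.4,
                           "independent", c(0.8, 1.1))
  ll_ind <- as.numeric(laplace_marginal_loglik(pari, d))
  expect_true(is.finite(ll_ind))
  expect_equal(agq_marginal_loglik(pari, d, nodes = 1), ll_ind,
               tolerance = 1e-8)
  # correlated with rho = 0 equals independent
  parc <- bivml_parameters(pari$beta1, pari$beta2, pari$alpha,
                           "correlated", c(0.8, 1.1, 0))
  expect_equal(as.numeric(laplace_marginal_loglik(parc, d)), ll_ind,
               tolerance = 1e-8)
  expect_equal(agq_marginal_loglik(pari, d, nodes = 15),
               agq_marginal_loglik(pari, d, nodes = 25),
               tolerance = 1e-5)
})

test_that("independent structure with alpha = 0 matches glmer", {
  skip_if_not_installed("lme4")
  tab <- model_fixture(12, 40, c(0.3, 0.5, -0.4), c(-0.2, 0.3, 0.6),
                       log_psi = 0, sigma = 0.9, seed = 33)
  f <- fit_bivml(tab, "grp", "grp", re_structure = "independent",
                 fix_alpha = 0, se = FALSE)
  df <- as.data.frame(tab)
  g1 <- lme4::glmer(y1 ~ grp + (1 | cluster), df, binomial, nAGQ = 1)
  g2 <- lme4::glmer(y2 ~ grp + (1 | cluster), df, binomial, nAGQ = 1)
  # with conditional independence the joint Laplace loglik separates
  expect_equal(f$loglik, as.numeric(logLik(g1)) + as.numeric(logLik(g2)),
               tolerance = 1e-4)
  expect_equal(unname(f$params_hat$beta1), unname(lme4::fixef(g1)),
               tolerance = 2e-3)
  expect_equal(unname(f$params_hat$beta2), unname(lme4::fixef(g2)),
               tolerance = 2e-3)
})

test_that("ICC follows the latent-threshold formula", {
  expect_equal(icc(pi^2 / 3), 0.5)
  expect_equal(icc(0), 0)
  expect_equal(icc(2.3824), 0.42, tolerance = 1e-3)
  expect_error(icc(-1), "sigma2")
  # strictly increasing
  s <- seq(0, 10, by = 0.5)
  expect_true(all(diff(icc(s)) > 0))
})

test_that("information criteria follow their definitions", {
  ic <- information_criteria(-100, 5, 400, 20)
  expect_equal(unname(ic["aic"]), 210)
  expect_equal(unname(ic["bic"]), 200 + 5 * log(20))
  ic2 <- information_criteria(-100, 5, 400, exp(2))
  expect_equal(unname(ic2["bic"]), 210)
  ic3 <- information_criteria(-100, 5, 400, 20, bic_n = "units")
  expect_equal(unname(ic3["bic"]), 200 + 5 * log(400))
})

test_that("null-model fit on a tiny table converges with a valid ICC", {
  tab <- model_fixture(2, 20, c(0.2, 0, 0), c(-0.2, 0, 0),
                       log_psi = 0.5, sigma = 0.5, seed = 5)
  f <- fit_bivml(tab)
  expect_equal(f$convergence$status, "converged")
  expect_true(f$icc >= 0 && f$icc < 1)
  expect_true(is.finite(f$aic) && is.finite(f$bic))
  expect_equal(f$n_clusters, 2)
  # AOR table transform consistency: exp of the coefficient CI
  a <- f$aor_table
  expect_equal(a$ci_low, exp(a$beta - qnorm(0.975) * a$se))
  expect_equal(a$aor, exp(a$beta))
})

test_that("single-cluster data refuses a multilevel fit", {
  df <- data.frame(y1 = rep(0:1, 10), y2 = rep(1:0, 10), cluster = "one")
  tab <- analysis_table(df)
  expect_error(fit_bivml(tab), "2 clusters")
})
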