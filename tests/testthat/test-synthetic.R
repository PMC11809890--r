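test_that("default configuration matches the emulated survey shape", {
  cfg <- default_emdhs_config()
  expect_equal(cfg$n_clusters, 68)
  expect_equal(cfg$n_clusters * cfg$cluster_size_mean, 3926, tolerance = 0.01)
  res <- Filter(function(cv) cv$name == "residence", cfg$covariates)[[1]]
  expect_equal(res$probs[res$levels == "rural"], 0.74, tolerance = 0.01)
  expect_equal(res$scope, "community")
  expect_equal(exp(cfg$true_log_psi), 6.381)
  expect_equal(cfg$true_sigma^2, 2.38)
  expect_error(default_emdhs_config(n_clusters = 0), "cluster")
})

test_that("simulation is deterministic given the seed", {
  cfg <- default_emdhs_config(n_clusters = 8, cluster_size_mean = 15,
                              seed = 77)
  a <- simulate_bivml(cfg)
  b <- simulate_bivml(cfg, seed = 77)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- simulate_bivml(cfg, seed = 78)
  expect_false(identical(as.data.frame(a), as.data.frame(c_)))
  # community covariates are constant within cluster
  expect_true(all(tapply(a$residence, a$zone,
                         function(v) length(unique(v))) == 1))
  # generated tables pass validation
  v <- validate_table(a)
  expect_true(v$multilevel_ok)
  expect_equal(v$n_clusters, 8)
})

test_that("the flat configuration reproduces uniform joint cells", {
  cfg <- default_emdhs_config(n_clusters = 40, cluster_size_mean = 100,
                              true_log_psi = 0, true_sigma = 0)
  cfg$true_beta1[] <- 0
  cfg$true_beta2[] <- 0
  tab <- simulate_bivml(cfg, seed = 4)
  jt <- joint_outcome_table(tab)
  se3 <- 3 * sqrt(0.25 * 0.75 / jt$total)
  expect_true(all(abs(jt$proportions - 0.25) < se3))
})

test_that("simulated crude odds ratio matches a brute-force oracle", {
  cfg <- default_emdhs_config()
  # oracle: an independent large-sample simulation at the same truth,
  # with the Plackett cells solved by vectorised bisection (not the
  # package's closed form)
  oracle_or <- withr::with_seed(1234, {
    nclus <- 20000; m <- 50
    u <- rep(rnorm(nclus, 0, cfg$true_sigma), each = m)
    n <- nclus * m
    X <- bivmlogit:::.config_design(cfg, local({
      df <- data.frame(row.names = seq_len(n))
      for (cv in cfg$covariates)
        df[[cv$name]] <- if (cv$scope == "community")
          rep(sample(cv$levels, nclus, TRUE, cv$probs), each = m)
        else sample(cv$levels, n, TRUE, cv$probs)
      df
    }))
    p1 <- plogis(drop(X %*% cfg$true_beta1[colnames(X)]) + u)
    p2 <- plogis(drop(X %*% cfg$true_beta2[colnames(X)]) + u)
    psi <- exp(cfg$true_log_psi)
    lo <- pmax(0, p1 + p2 - 1); hi <- pmin(p1, p2)
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      g <- mid * (1 - p1 - p2 + mid) - psi * (p1 - mid) * (p2 - mid)
      up <- g > 0
      hi[up] <- mid[up]; lo[!up] <- mid[!up]
    }
    p11 <- (lo + hi) / 2
    r <- runif(n)
    y1 <- r < p1
    y2 <- r < p11 | (r >= p1 & r < p1 + (p2 - p11))
    # note: cell order here is (11), (10), (01), (00) via thresholds
    n11 <- as.numeric(sum(y1 & y2)); n10 <- as.numeric(sum(y1 & !y2))
    n01 <- as.numeric(sum(!y1 & y2)); n00 <- as.numeric(sum(!y1 & !y2))
    (n11 * n00) / (n10 * n01)
  })
  ors <- vapply(1:20, function(s) {
    jt <- joint_outcome_table(simulate_bivml(cfg, seed = s))
    contingency_odds_ratio(jt)$or_hat
  }, 0)
  mc_se <- sd(ors) / sqrt(length(ors))
  expect_lt(abs(mean(ors) - oracle_or), 3 * mc_se)
})

test_that("within-cluster outcome correlation rises with sigma^2", {
  icc_emp <- function(sig2, seed) {
    cfg <- default_emdhs_config(n_clusters = 30, cluster_size_mean = 40,
                                true_sigma = sqrt(sig2))
    tab <- simulate_bivml(cfg, seed = seed)
    p <- tapply(tab$anc4, tab$zone, mean)
    stats::var(p)   # between-cluster spread of prevalences
  }
  spread <- sapply(c(0, 1, 4), function(s2)
    mean(sapply(1:10, function(sd_) icc_emp(s2, sd_))))
  expect_true(all(diff(spread) > 0))
})

test_that("configurations round-trip through YAML", {
  cfg <- default_emdhs_config(seed = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$true_beta1, cfg$true_beta1)
  expect_equal(back$n_clusters, cfg$n_clusters)
  expect_identical(as.data.frame(simulate_bivml(back)),
                   as.data.frame(simulate_bivml(cfg)))
})

test_that("a tiny recovery experiment reports every free parameter", {
  cfg <- default_emdhs_config(n_clusters = 12, cluster_size_mean = 15)
  cfg$covariates <- cfg$covariates[4]         # residence only
  cfg$true_beta1 <- cfg$true_beta1[c("(Intercept)", "residencerural")]
  cfg$true_beta2 <- cfg$true_beta2[c("(Intercept)", "residencerural")]
  rec <- recovery_experiment(cfg, seeds = 1:2, se = FALSE)
  expect_equal(nrow(rec$estimates), 2)
  # free parameters: 2 + 2 betas + alpha + log sigma
  expect_equal(nrow(rec$summary), 6)
  expect_true(all(is.finite(rec$summary$mean_est)))
})
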