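# Shared fixtures, all built in code.

# the published weighted joint 2x2 of the motivating survey, encoded as
# four weighted pseudo-units: (anc4, facility) with weight = cell count
survey_joint_fixture <- function() {
  df <- data.frame(
    anc4     = c(1, 1, 0, 0),
    facility = c(1, 0, 1, 0),
    zone     = c("Z1", "Z1", "Z2", "Z2"),
    weight   = c(1266, 422, 796, 1442))
  analysis_table(df, outcome1 = "anc4", outcome2 = "facility",
                 cluster = "zone", weight = "weight")
}

# small synthetic two-cluster table with a 3-level covariate
small_table <- function(n = 40, seed = 42, n_clusters = 2) {
  df <- withr::with_seed(seed, data.frame(
    y1 = rbinom(n, 1, 0.45),
    y2 = rbinom(n, 1, 0.55),
    cluster = sample(paste0("c", seq_len(n_clusters)), n, replace = TRUE),
    grp = sample(c("a", "b", "c"), n, replace = TRUE),
    weight = 1))
  analysis_table(df, "y1", "y2", "cluster", "weight",
                 schema = list(categorical_spec("grp", c("a", "b", "c"))))
}

grp_schema <- list(categorical_spec("grp", c("a", "b", "c")))

# fixture generated from the model itself with chosen truth (a 3-level
# covariate; beta = c(intercept, effect_b, effect_c) per outcome);
# written independently of simulate_bivml so the generator and the fitter
# can cross-check each other
model_fixture <- function(n_clusters, per_cluster, beta1, beta2,
                          log_psi = 0, sigma = 0, seed = 1) {
  n <- n_clusters * per_cluster
  withr::with_seed(seed, {
    grp <- sample(c("a", "b", "c"), n, replace = TRUE)
    u <- rnorm(n_clusters, 0, sigma)
    cl <- rep(seq_len(n_clusters), each = per_cluster)
    eff <- function(beta) beta[1] +
      beta[2] * (grp == "b") + beta[3] * (grp == "c")
    eta1 <- eff(beta1) + u[cl]
    eta2 <- eff(beta2) + u[cl]
    cells <- plackett_cells(plogis(eta1), plogis(eta2), exp(log_psi))
    r <- runif(n)
    y1 <- as.integer(r < cells$p11 + cells$p10)
    y2 <- as.integer(r < cells$p11 | (r >= cells$p11 + cells$p10 &
                       r < cells$p11 + cells$p10 + cells$p01))
    df <- data.frame(y1 = y1, y2 = y2, grp = grp, cluster = cl)
  })
  analysis_table(df, "y1", "y2", "cluster", schema = grp_schema)
}
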