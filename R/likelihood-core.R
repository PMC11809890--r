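# Lean vectorised likelihood core used by the estimation routines.
# A "context" freezes everything that is constant during a random-effect
# mode search (linear predictor offsets, outcomes, weights, cluster
# grouping, psi), so the inner Newton iterations touch only vector
# arithmetic.  Units are re-sorted by cluster once, letting per-cluster
# sums run off a single cumsum instead of a grouped aggregation.

# p11 from margins and psi, numeric-only fast path (same algebra as
# .plackett_p11, without the data.frame wrapper or the bisection guard;
# inputs from the inverse logit are always interior so the closed forms
# apply).  psi is scalar here (intercept-only association).
.p11_fast <- function(p1, p2, psi) {
  a <- 1 + (p1 + p2) * (psi - 1)
  disc <- a * a - 4 * psi * (psi - 1) * p1 * p2
  disc[disc < 0] <- 0
  D <- sqrt(disc)
  .p11_fast_root(p1, p2, psi, a, D)
}

.p11_fast_root <- function(p1, p2, psi, a, D) {
  r <- 2 * psi * p1 * p2 / (a + D)
  if (psi < 1) { neg <- a <= 0; r[neg] <- (a[neg] - D[neg]) / (2 * (psi - 1)) }
  r
}

.make_ctx <- function(params, design, weighted = FALSE) {
  ci <- design$cluster_index
  ord <- if (is.unsorted(ci)) order(ci) else seq_along(ci)
  ci <- ci[ord]
  n <- length(ci)
  ends <- c(which(ci[-1] != ci[-n]), n)
  y1 <- design$y1[ord]; y2 <- design$y2[ord]
  list(xb1 = drop(design$X1 %*% params$beta1)[ord],
       xb2 = drop(design$X2 %*% params$beta2)[ord],
       psi = exp(params$alpha),
       y1 = y1, y2 = y2,
       w = if (weighted) design$weight[ord] else NULL,
       ci = ci,
       nc = length(design$cluster_levels),
       ends = ends, ids = ci[ends],
       sel_sign = (2 * y1 - 1) * (2 * y2 - 1),
       d1_sign = (1 - y2) * (2 * y1 - 1),   # coef of 1 in dp_sel/dp1
       d2_sign = (1 - y1) * (2 * y2 - 1),
       params = params)
}

# sum a per-unit vector into per-cluster slots (units sorted by cluster)
.by_cluster <- function(ctx, v) {
  out <- numeric(ctx$nc)
  cs <- cumsum(v)[ctx$ends]
  out[ctx$ids] <- cs - c(0, cs[-length(cs)])
  out
}

# expand cluster effects to unit level: returns list(e1, e2)
.ctx_unit_u <- function(ctx, u) {
  if (is.matrix(u)) list(e1 = u[ctx$ci, 1], e2 = u[ctx$ci, 2])
  else { e <- u[ctx$ci]; list(e1 = e, e2 = e) }
}

# per-cluster data log-likelihood at cluster effects u
.ctx_data_ll <- function(ctx, u) {
  uu <- .ctx_unit_u(ctx, u)
  p1 <- 1 / (1 + exp(-(ctx$xb1 + uu$e1)))
  p2 <- 1 / (1 + exp(-(ctx$xb2 + uu$e2)))
  p11 <- .p11_fast(p1, p2, ctx$psi)
  c0 <- ctx$y1 * (1 - ctx$y2) * p1 + (1 - ctx$y1) * ctx$y2 * p2 +
    (1 - ctx$y1) * (1 - ctx$y2) * (1 - p1 - p2)
  p_sel <- c0 + ctx$sel_sign * p11
  p_sel[p_sel < 1e-300] <- 1e-300   # rounding can graze zero at the bounds
  ll <- log(p_sel)
  if (!is.null(ctx$w)) ll <- ll * ctx$w
  .by_cluster(ctx, ll)
}

# per-cluster gradient of the data log-likelihood w.r.t. u
# (vector for shared, nc x 2 matrix otherwise)
.ctx_data_grad <- function(ctx, u) {
  uu <- .ctx_unit_u(ctx, u)
  p1 <- 1 / (1 + exp(-(ctx$xb1 + uu$e1)))
  p2 <- 1 / (1 + exp(-(ctx$xb2 + uu$e2)))
  psi <- ctx$psi
  a <- 1 + (p1 + p2) * (psi - 1)
  disc <- a * a - 4 * psi * (psi - 1) * p1 * p2
  disc[disc < 0] <- 0
  D <- sqrt(disc)
  p11 <- .p11_fast_root(p1, p2, psi, a, D)
  d11p1 <- 0.5 * (1 - (a - 2 * psi * p2) / D)
  d11p2 <- 0.5 * (1 - (a - 2 * psi * p1) / D)
  c0 <- ctx$y1 * (1 - ctx$y2) * p1 + (1 - ctx$y1) * ctx$y2 * p2 +
    (1 - ctx$y1) * (1 - ctx$y2) * (1 - p1 - p2)
  p_sel <- c0 + ctx$sel_sign * p11
  p_sel[p_sel < 1e-300] <- 1e-300
  dd1 <- (ctx$d1_sign + ctx$sel_sign * d11p1) * p1 * (1 - p1) / p_sel
  dd2 <- (ctx$d2_sign + ctx$sel_sign * d11p2) * p2 * (1 - p2) / p_sel
  if (!is.null(ctx$w)) { dd1 <- dd1 * ctx$w; dd2 <- dd2 * ctx$w }
  if (is.matrix(u)) cbind(.by_cluster(ctx, dd1), .by_cluster(ctx, dd2))
  else .by_cluster(ctx, dd1 + dd2)
}

.ctx_obj <- function(ctx, u) {
  .ctx_data_ll(ctx, u) + .re_prior(ctx$params, u)$logd
}

.ctx_obj_grad <- function(ctx, u) {
  .ctx_data_grad(ctx, u) + .re_prior(ctx$params, u)$grad
}
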