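test_that("a group-only design recovers the two-group mean difference", {
  set.seed(1)
  m <- toy_beta(matrix(rnorm(5 * 10), 5, 10))
  labels <- toy_labels(m, 4)
  design <- cbind(intercept = 1, group = as.numeric(labels == "case"))
  rownames(design) <- colnames(m)
  fit <- fit_linear_models(m, design)
  expect_equal(fit$coef,
               rowMeans(m[, 1:4]) - rowMeans(m[, 5:10]),
               ignore_attr = TRUE)
  expect_equal(unique(fit$df_resid), 8)
})

test_that("an exact linear response has zero residual variance", {
  design <- cbind(intercept = 1, group = c(1, 1, 1, 0, 0, 0),
                  cov = c(0.1, 0.2, 0.3, 0.1, 0.2, 0.4))
  rownames(design) <- sprintf("s%02d", 1:6)
  m <- toy_beta(matrix(2 + 3 * design[, "group"] - design[, "cov"],
                       1, 6, byrow = TRUE), samples = rownames(design))
  fit <- fit_linear_models(m, design)
  expect_equal(fit$s_sq, 0, tolerance = 1e-20)
  expect_equal(fit$coef, 3)
})

test_that("coefficients agree with a normal-equations solve", {
  set.seed(2)
  design <- cbind(intercept = 1, group = c(1, 1, 1, 0, 0, 0),
                  cov = runif(6))
  rownames(design) <- sprintf("s%02d", 1:6)
  m <- toy_beta(matrix(rnorm(12), 2, 6), samples = rownames(design))
  fit <- fit_linear_models(m, design)
  for (i in 1:2) {
    bhat <- solve(crossprod(design), crossprod(design, m[i, ]))
    resid <- m[i, ] - design %*% bhat
    expect_equal(fit$coef[i], unname(bhat["group", 1]))
    expect_equal(fit$s_sq[i], sum(resid^2) / 3)
    expect_equal(fit$se[i], sqrt(solve(crossprod(design))["group", "group"]))
  }
})

test_that("degenerate designs and non-finite inputs are rejected", {
  design <- cbind(intercept = 1, group = c(1, 1, 0, 0),
                  dup = c(1, 1, 0, 0))
  m <- toy_beta(matrix(rnorm(8), 2, 4))
  expect_error(fit_linear_models(m, design), "rank")
  good <- design[, 1:2]
  m[1, 1] <- Inf
  expect_error(fit_linear_models(m, good), "non-finite")
})

test_that("identical residual variances give a degenerate prior", {
  prior <- estimate_prior(rep(2.5, 50), df_resid = 10)
  expect_identical(prior$d0, Inf)
  expect_equal(prior$s0_sq, 2.5)
})

test_that("the prior recovers a known scaled-F generator", {
  set.seed(3)
  d0 <- 8
  s0 <- 0.5
  dg <- 10
  n <- 50000
  s_sq <- s0 * (stats::rchisq(n, dg) / dg) / (stats::rchisq(n, d0) / d0)
  prior <- estimate_prior(s_sq, df_resid = dg)
  expect_lt(abs(prior$d0 - d0) / d0, 0.15)
  expect_lt(abs(prior$s0_sq - s0) / s0, 0.05)
})

test_that("moment equations match an independent root-finding oracle", {
  s_sq <- c(0.4, 0.9, 1.7, 2.6, 0.2, 1.1, 0.8, 1.4, 2.1, 0.6, 3.0, 0.3)
  dg <- 6
  prior <- estimate_prior(s_sq, df_resid = dg)
  # oracle: invert the trigamma moment equation with uniroot, independently
  e <- log(s_sq) - digamma(dg / 2) + log(dg / 2)
  target <- stats::var(e) - trigamma(dg / 2)
  expect_gt(target, 0)
  root <- stats::uniroot(function(x) trigamma(x) - target,
                         c(1e-6, 1e6), tol = 1e-12)$root
  expect_equal(prior$d0, 2 * root, tolerance = 1e-6)
  expect_equal(prior$s0_sq,
               exp(mean(e) + digamma(root) - log(root)),
               tolerance = 1e-6)
})

test_that("estimate_prior refuses fewer than 10 usable probes", {
  expect_error(estimate_prior(rep(1, 9), 5), "at least 10")
  expect_error(estimate_prior(c(rep(0, 20), rep(1, 5)), 5), "at least 10")
})

test_that("moderation limits recover the ordinary and fully shrunk tests", {
  set.seed(4)
  stats <- tibble::tibble(
    probe_id = sprintf("p%02d", 1:20),
    coef = rnorm(20), se = runif(20, 0.2, 1),
    s_sq = stats::rchisq(20, 5) / 5, df_resid = 5
  )
  ord <- moderate(stats, list(d0 = 0, s0_sq = 1))
  expect_equal(ord$t_mod, stats$coef / (stats$se * sqrt(stats$s_sq)))
  expect_equal(ord$p, 2 * pt(-abs(ord$t_mod), df = 5))

  full <- moderate(stats, list(d0 = Inf, s0_sq = 0.7))
  expect_equal(full$t_mod, stats$coef / (stats$se * sqrt(0.7)))
  expect_equal(full$p, 2 * pnorm(-abs(full$t_mod)))
})

test_that("the shrinkage formula matches its hand-evaluated example", {
  stats <- tibble::tibble(probe_id = "p1", coef = 1, se = 0.5,
                          s_sq = 1, df_resid = 4)
  out <- moderate(stats, list(d0 = 4, s0_sq = 1))
  # s2_post = (4*1 + 4*1)/8 = 1; t = 1/(0.5*1) = 2; p on 8 df
  expect_equal(out$t_mod, 2)
  expect_equal(out$p, 2 * pt(-2, df = 8))
  expect_error(moderate(dplyr::mutate(stats, se = 0),
                        list(d0 = 4, s0_sq = 1)), "standard error")
})

test_that("shrunk variances stay between the probe and prior variances", {
  set.seed(5)
  s_sq <- stats::rchisq(200, 6) / 6
  prior <- estimate_prior(s_sq, 6)
  s2_post <- (prior$d0 * prior$s0_sq + 6 * s_sq) / (prior$d0 + 6)
  lo <- pmin(s_sq, prior$s0_sq)
  hi <- pmax(s_sq, prior$s0_sq)
  expect_true(all(s2_post >= lo - 1e-12 & s2_post <= hi + 1e-12))
})

test_that("BH adjustment handles its boundary cases", {
  expect_identical(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_identical(bh_adjust(numeric(0)), numeric(0))
})

test_that("BH adjustment commutes with permutation and is bounded", {
  set.seed(6)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) <= 1))
  expect_true(all(bh_adjust(p) >= p))
})

test_that("beta-scale differences behave on constant groups", {
  beta <- toy_beta(cbind(matrix(0.30, 3, 2), matrix(0.40, 3, 3)))
  labels <- toy_labels(beta, 2)
  db <- delta_beta(beta, labels)
  expect_equal(db$delta_beta, rep(-0.10, 3))
  same <- toy_beta(matrix(0.5, 3, 4))
  expect_equal(delta_beta(same, toy_labels(same, 2))$delta_beta, rep(0, 3))
  expect_error(delta_beta(beta, stats::setNames(rep("case", 5),
                                                colnames(beta))),
               "nonempty")
})

test_that("signature delta signs match the simulation truth", {
  cfg <- tiny_config(n_probes = 2000, n_signature = 100, n_cases = 12,
                     n_controls = 36, hypo_fraction = 0.5, noise_sd = 0.3,
                     seed = 81)
  sim <- generate_dataset(cfg)
  keep <- sim$samples$group %in% c("case", "control_pool")
  labels <- stats::setNames(
    ifelse(sim$samples$group[keep] == "case", "case", "control"),
    sim$samples$sample_id[keep]
  )
  db <- delta_beta(sim$beta, labels)
  sig <- sim$truth$signature_probes
  emp <- db$delta_beta[match(sig, db$probe_id)]
  agree <- mean(sign(emp) == sign(sim$truth$true_delta[sig]))
  expect_gte(agree, 0.95)
})

test_that("the assembled fit exposes tidy and glance views", {
  sim <- generate_dataset(tiny_config(seed = 91))
  mr <- select_controls(sim$samples, ratio = 4)
  fit <- diff_methylation(sim$beta, sim$samples, match_labels(mr))
  td <- tidy(fit)
  expect_true(all(c("probe_id", "delta_beta", "t_mod", "p", "p_adj", "auc")
                  %in% names(td)))
  expect_true(all(td$p_adj >= td$p))
  expect_true(all(td$p >= 0 & td$p <= 1))
  gl <- glance(fit)
  expect_identical(gl$n_probes, nrow(sim$beta))
  expect_identical(gl$n_cases, 6L)
  expect_identical(gl$n_controls, 24L)
})
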