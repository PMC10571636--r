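test_that("ROC importance matches pair enumeration and its extremes", {
  expect_equal(probe_auc(c(0.2, 0.3), c(0.25, 0.4)), 0.75)
  expect_equal(probe_auc(c(0.1, 0.2), c(0.5, 0.6)), 1)   # full separation
  expect_equal(probe_auc(c(0.5, 0.5), c(0.5, 0.5)), 0.5) # all ties
  # direction-free: hypermethylated separation scores identically
  expect_equal(probe_auc(c(0.8, 0.9), c(0.2, 0.3)), 1)
  expect_error(probe_auc(numeric(0), 1), "nonempty")
})

test_that("ROC importance agrees with an independent AUC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:5) {
    case <- rnorm(7, mean = 0.4, sd = 0.15)
    ctrl <- rnorm(12, mean = 0.55, sd = 0.15)
    ref <- as.numeric(pROC::auc(
      response = c(rep(0, 7), rep(1, 12)),
      predictor = c(case, ctrl),
      direction = "<", quiet = TRUE
    ))
    expect_equal(probe_auc(case, ctrl), max(ref, 1 - ref))
  }
})

test_that("vectorized importance equals the scalar computation", {
  set.seed(12)
  beta <- toy_beta(matrix(runif(8 * 10), 8, 10))
  labels <- toy_labels(beta, 4)
  tab <- tibble::tibble(probe_id = rownames(beta))
  filled <- add_probe_importance(tab, beta, labels)
  by_hand <- vapply(rownames(beta), function(pid) {
    probe_auc(beta[pid, names(labels)[labels == "case"]],
              beta[pid, names(labels)[labels == "control"]])
  }, numeric(1))
  expect_equal(filled$auc, unname(by_hand))
})

test_that("probe selection applies its four stages in order", {
  beta <- toy_beta(rbind(
    c(0.10, 0.12, 0.60, 0.62, 0.61, 0.63),  # strong, uncorrelated noise-free
    c(0.20, 0.22, 0.70, 0.72, 0.71, 0.73),
    c(0.48, 0.50, 0.52, 0.54, 0.53, 0.55)   # |delta| = 0.04 -> excluded
  ))
  labels <- toy_labels(beta, 2)
  tab <- tibble::tibble(
    probe_id = rownames(beta),
    delta_beta = c(-0.50, -0.50, -0.04),
    p = c(1e-6, 1e-5, 1e-8)
  )
  tab <- add_probe_importance(tab, beta, labels)
  # r_max = 1 disables pruning so the delta floor and p-ordering show alone
  got <- select_probes(tab, beta, selection_params(top_n = 10, r_max = 1))
  expect_identical(got, c("p01", "p02"))  # p order, delta floor enforced

  # a duplicated probe (r = 1) is pruned down to one copy; p02 shares only
  # the group structure with p01 (r ~ 0.94), so it survives the ceiling
  beta2 <- rbind(beta[1, , drop = FALSE],
                 c(0.30, 0.14, 0.80, 0.64, 0.76, 0.66),
                 beta[1, , drop = FALSE] + 0.001)
  rownames(beta2) <- c("p01", "p02", "p01copy")
  tab2 <- tibble::tibble(
    probe_id = rownames(beta2),
    delta_beta = c(-0.5, -0.5, -0.5),
    p = c(1e-6, 1e-5, 1e-4)
  )
  tab2 <- add_probe_importance(tab2, beta2, labels)
  # the shifted copy is perfectly correlated with p01 (r = 1); p02 shares
  # only the group structure, so a ceiling just under 1 prunes the copy alone
  got2 <- select_probes(tab2, beta2, selection_params(top_n = 10,
                                                      r_max = 0.95))
  expect_identical(got2, c("p01", "p02"))

  # nothing reaches the delta floor -> explicit error
  expect_error(
    select_probes(tab[3, ], beta, selection_params()),
    "No candidate probes"
  )
})

test_that("mutually uncorrelated passing probes are all retained in p order", {
  set.seed(13)
  n <- 12
  beta <- toy_beta(matrix(runif(6 * n), 6, n))
  beta[1:4, 1:4] <- beta[1:4, 1:4] * 0.2          # cases low at probes 1-4
  labels <- toy_labels(beta, 4)
  tab <- tibble::tibble(
    probe_id = rownames(beta),
    delta_beta = c(-0.3, -0.25, -0.28, -0.26, 0.01, 0.0),
    p = c(2e-4, 1e-6, 5e-5, 3e-3, 0.4, 0.9)
  )
  tab <- add_probe_importance(tab, beta, labels)
  got <- select_probes(tab, beta, selection_params(auc_min = 0.5,
                                                   r_max = 1))
  expect_identical(got, c("p02", "p03", "p01", "p04"))
})

test_that("the clustering score matches its one-dimensional hand case", {
  beta <- toy_beta(matrix(c(0, 1, 10, 11), 1, 4))
  labels <- toy_labels(beta, 2)
  sc <- clustering_score(beta, "p01", labels)
  expect_equal(sc$gap, 9)
  expect_equal(sc$spread_case, 0.5)
  expect_equal(sc$spread_control, 0.5)
  expect_equal(sc$score, 9 / (1 + 1e-8))
})

test_that("the clustering score is symmetric, zero on contact, and scales", {
  set.seed(14)
  beta <- toy_beta(matrix(runif(40), 5, 8))
  labels <- toy_labels(beta, 3)
  flipped <- stats::setNames(
    ifelse(labels == "case", "control", "case"), names(labels)
  )
  a <- clustering_score(beta, rownames(beta), labels)
  b <- clustering_score(beta, rownames(beta), flipped)
  expect_equal(a$score, b$score)
  expect_equal(a$gap, b$gap)

  # shared identical sample across groups -> zero gap and score
  touch <- beta
  touch[, 4] <- touch[, 1]
  sc0 <- clustering_score(touch, rownames(touch), labels)
  expect_equal(sc0$gap, 0)
  expect_equal(sc0$score, 0)

  # translation invariance and linear scaling
  shifted <- clustering_score(beta + 0.3, rownames(beta), labels)
  expect_equal(shifted$score, a$score)
  doubled <- clustering_score(beta * 2, rownames(beta), labels)
  expect_equal(doubled$gap, 2 * a$gap)
  expect_equal(doubled$score, a$score, tolerance = 1e-6)
})

test_that("grid search returns the single-combination profile unchanged", {
  sim <- generate_dataset(tiny_config(n_probes = 800, n_signature = 40,
                                      seed = 15))
  mr <- select_controls(sim$samples, ratio = 4)
  labels <- match_labels(mr)
  fit <- diff_methylation(sim$beta, sim$samples, labels)
  beta_train <- sim$beta[, names(labels)]
  params <- selection_params(top_n = 50, auc_min = 0.8, r_max = 0.9)
  prof <- grid_search(fit$table, beta_train, labels, grid = list(params))
  tab <- add_probe_importance(fit$table, beta_train, labels)
  expect_identical(prof$probe_ids, select_probes(tab, beta_train, params))
  expect_identical(unclass(prof$params), unclass(params))
  expect_identical(prof$n_evaluated, 1L)
})

test_that("grid search prefers separating probes over null probes", {
  sim <- generate_dataset(tiny_config(n_probes = 1500, n_signature = 60,
                                      n_cases = 10, n_controls = 40,
                                      seed = 16))
  mr <- select_controls(sim$samples, ratio = 4)
  labels <- match_labels(mr)
  fit <- diff_methylation(sim$beta, sim$samples, labels)
  beta_train <- sim$beta[, names(labels)]
  # permissive combination finds the signature; strict AUC on shuffled-p
  # nonsense cannot beat it
  good <- selection_params(top_n = 100, auc_min = 0.75, r_max = 0.9)
  bad <- selection_params(top_n = 5, auc_min = 0.99, r_max = 0.9)
  prof <- grid_search(fit$table, beta_train, labels, grid = list(bad, good))
  expect_identical(prof$n_evaluated + prof$n_skipped, 2L)
  truth <- sim$truth$signature_probes
  expect_gt(mean(prof$probe_ids %in% truth), 0.8)
  # the returned profile is the argmax over the evaluated combinations
  tab <- add_probe_importance(fit$table, beta_train, labels)
  for (params in list(bad, good)) {
    probes <- tryCatch(select_probes(tab, beta_train, params),
                       episig_no_candidates = function(e) character(0))
    if (length(probes) > 0) {
      expect_lte(clustering_score(beta_train, probes, labels)$score,
                 prof$score$score)
    }
  }
})

test_that("score ties break toward the smaller parameter tuple", {
  beta <- toy_beta(matrix(c(0.1, 0.12, 0.6, 0.62, 0.61, 0.60), 1, 6))
  labels <- toy_labels(beta, 2)
  tab <- tibble::tibble(probe_id = "p01", delta_beta = -0.5, p = 1e-5)
  tab <- add_probe_importance(tab, beta, labels)
  p_small <- selection_params(top_n = 10, auc_min = 0.75, r_max = 0.7)
  p_large <- selection_params(top_n = 10, auc_min = 0.75, r_max = 0.9)
  prof <- grid_search(tab, beta, labels, grid = list(p_large, p_small))
  expect_equal(prof$params$r_max, 0.7)
})

test_that("clustering evaluation separates clean synthetic groups", {
  sim <- generate_dataset(tiny_config(n_probes = 600, n_signature = 40,
                                      noise_sd = 0.15, seed = 17))
  keep <- sim$samples$group %in% c("case", "control_pool")
  labels <- stats::setNames(
    ifelse(sim$samples$group[keep] == "case", "case", "control"),
    sim$samples$sample_id[keep]
  )
  ev <- evaluate_clustering(sim$beta, sim$truth$signature_probes, labels)
  expect_equal(ev$purity, 1.0)
  expect_s3_class(ev$hclust, "hclust")
  expect_identical(nrow(ev$mds), length(labels))
})

test_that("permuted labels on null data give chance-level purity", {
  set.seed(18)
  sim <- generate_dataset(tiny_config(n_probes = 500, n_signature = 0,
                                      n_cases = 8, n_controls = 24,
                                      seed = 18))
  keep <- sim$samples$group %in% c("case", "control_pool")
  ids <- sim$samples$sample_id[keep]
  purities <- replicate(20, {
    labels <- stats::setNames(
      sample(c(rep("case", 8), rep("control", 24))), ids
    )
    evaluate_clustering(sim$beta, rownames(sim$beta)[1:50], labels)$purity
  })
  # chance level is the max-class fraction, 24/32
  expect_lt(abs(mean(purities) - 24 / 32), 0.08)
})

test_that("MDS embeds three equidistant samples isometrically", {
  beta <- toy_beta(matrix(c(1, 0, 0,
                            0, 1, 0,
                            0, 0, 1), 3, 3, byrow = TRUE))
  labels <- stats::setNames(c("case", "control", "control"), colnames(beta))
  ev <- evaluate_clustering(beta, rownames(beta), labels)
  xy <- as.matrix(ev$mds[, c("mds1", "mds2")])
  d <- as.numeric(dist(xy))
  expect_equal(d, rep(sqrt(2), 3), tolerance = 1e-8)
  expect_error(evaluate_clustering(beta[, 1:2],
                                   rownames(beta),
                                   labels[1:2]),
               "at least 3")
})
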