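#' Selection parameters for signature probes
#'
#' @param delta_min Minimum absolute beta-scale methylation difference
#'   (default 0.05, i.e. the conventional 5% floor).
#' @param top_n Number of probes kept by p-value rank.
#' @param auc_min Minimum direction-free ROC importance in `[0.5, 1]`.
#' @param r_max Maximum allowed absolute pairwise Pearson correlation among
#'   selected probes.
#' @return A `selection_params` list.
#' @export
selection_params <- function(delta_min = 0.05, top_n = 200,
                             auc_min = 0.75, r_max = 0.8) {
  if (delta_min <= 0 || delta_min > 0.5) {
    abort("`delta_min` must lie in (0, 0.5].")
  }
  if (auc_min < 0.5 || auc_min > 1) abort("`auc_min` must lie in [0.5, 1].")
  if (r_max <= 0 || r_max > 1) abort("`r_max` must lie in (0, 1].")
  if (top_n < 2) abort("`top_n` must be at least 2.")
  structure(list(delta_min = delta_min, top_n = as.integer(top_n),
                 auc_min = auc_min, r_max = r_max),
            class = "selection_params")
}

#' Direction-free ROC importance of one probe
#'
#' The probability that a random control value exceeds a random case value,
#' counting ties as one half (the Mann-Whitney AUC), folded to be
#' direction-free: `importance = max(A, 1 - A)`, so both hypo- and
#' hypermethylated probes score by separability alone.
#'
#' @param case_values,control_values Nonempty numeric vectors.
#' @return Importance in `[0.5, 1]`.
#' @export
#' @examples
#' probe_auc(c(0.2, 0.3), c(0.25, 0.4))  # 0.75
probe_auc <- function(case_values, control_values) {
  if (length(case_values) == 0 || length(control_values) == 0) {
    abort("Both groups must be nonempty.")
  }
  n1 <- length(control_values)
  n2 <- length(case_values)
  r <- rank(c(control_values, case_values))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  a <- u / (n1 * n2)
  max(a, 1 - a)
}

# Vectorized ROC importance over the rows of a beta matrix.
probe_auc_matrix <- function(beta, labels) {
  ids <- names(labels)
  ctrl <- ids[labels == "control"]
  case <- ids[labels == "case"]
  sub <- beta[, c(ctrl, case), drop = FALSE]
  n1 <- length(ctrl)
  n2 <- length(case)
  ranks <- t(apply(sub, 1, rank))
  u <- rowSums(ranks[, seq_len(n1), drop = FALSE]) - n1 * (n1 + 1) / 2
  a <- u / (n1 * n2)
  pmax(a, 1 - a)
}

#' Fill the ROC-importance column of a differential methylation table
#'
#' @param table Tibble with a `probe_id` column (the `table` of a
#'   [diff_methylation()] fit).
#' @param beta Beta matrix containing the training samples.
#' @param labels Named `"case"`/`"control"` vector.
#' @return `table` with its `auc` column populated.
#' @export
add_probe_importance <- function(table, beta, labels) {
  assert_beta_matrix(beta)
  imp <- probe_auc_matrix(beta[table$probe_id, , drop = FALSE], labels)
  table$auc <- unname(imp)
  table
}

#' Select signature probes
#'
#' Sequential selection pipeline: (1) keep probes with
#' `|delta_beta| >= delta_min`; (2) keep probes with ROC importance
#' `>= auc_min`; (3) order by p-value (ties by larger `|delta_beta|`, then
#' probe id) and keep the first `top_n`; (4) greedy correlation pruning —
#' walk the ordered list and drop any probe whose absolute Pearson
#' correlation with an already-retained probe exceeds `r_max`, computed
#' across all training samples.
#'
#' @param table Differential methylation tibble with `probe_id`,
#'   `delta_beta`, `p`, and a populated `auc` column (see
#'   [add_probe_importance()]).
#' @param beta Beta matrix restricted to the training samples (used for the
#'   correlation pruning).
#' @param params A [selection_params()] object.
#' @return Ordered character vector of retained probe ids (possibly empty
#'   after steps 2-4).
#' @export
select_probes <- function(table, beta, params = selection_params()) {
  stopifnot(inherits(params, "selection_params"))
  cand <- dplyr::filter(table, abs(.data$delta_beta) >= params$delta_min)
  if (nrow(cand) == 0) {
    abort(sprintf(
      "No candidate probes: none reach |delta beta| >= %.3g.",
      params$delta_min
    ), class = "episig_no_candidates")
  }
  if (any(is.na(cand$auc))) {
    abort("`auc` column not populated; run add_probe_importance() first.")
  }
  cand <- dplyr::filter(cand, .data$auc >= params$auc_min)
  if (nrow(cand) == 0) return(character(0))
  cand <- cand[order(cand$p, -abs(cand$delta_beta), cand$probe_id), ]
  cand <- utils::head(cand, params$top_n)

  ids <- cand$probe_id
  if (length(ids) <= 1 || params$r_max >= 1) return(ids)
  cmat <- abs(suppressWarnings(cor(t(beta[ids, , drop = FALSE]))))
  cmat[is.na(cmat)] <- 0  # constant probes carry no redundancy
  keep <- logical(length(ids))
  for (i in seq_along(ids)) {
    keep[i] <- !any(cmat[i, keep] > params$r_max)
  }
  ids[keep]
}

#' Clustering-quality score of a probe set
#'
#' Samples are represented as beta vectors over the selected probes. The
#' score contrasts the minimum Euclidean distance between any case-control
#' pair (the gap) with the two groups' dispersions (root-mean-square
#' distance of each group's samples to its centroid):
#' `score = gap / (spread_case + spread_control + 1e-8)`. Larger is better;
#' 0 means the groups touch. The score is symmetric in the group labels,
#' invariant to translation and rotation of probe space, and scales
#' linearly with the data.
#'
#' @param beta Beta matrix containing the labelled samples.
#' @param probes Nonempty character vector of probe ids.
#' @param labels Named `"case"`/`"control"` vector.
#' @return A `clustering_score` list: `gap`, `spread_case`,
#'   `spread_control`, `score`.
#' @export
clustering_score <- function(beta, probes, labels) {
  if (length(probes) == 0) abort("`probes` must be nonempty.")
  ids <- names(labels)
  case_ids <- ids[labels == "case"]
  ctrl_ids <- ids[labels == "control"]
  if (length(case_ids) == 0 || length(ctrl_ids) == 0) {
    abort("Both groups need at least one sample.")
  }
  X <- t(beta[probes, ids, drop = FALSE])  # samples x probes
  xc <- X[case_ids, , drop = FALSE]
  xk <- X[ctrl_ids, , drop = FALSE]

  # minimum inter-group distance
  cross <- outer(rowSums(xc^2), rowSums(xk^2), "+") - 2 * xc %*% t(xk)
  gap <- sqrt(max(min(cross), 0))

  rms_spread <- function(g) {
    if (nrow(g) <= 1) return(0)
    ctr <- colMeans(g)
    sqrt(mean(rowSums(sweep(g, 2, ctr)^2)))
  }
  sc <- rms_spread(xc)
  sk <- rms_spread(xk)
  structure(
    list(gap = gap, spread_case = sc, spread_control = sk,
         score = gap / (sc + sk + 1e-8)),
    class = "clustering_score"
  )
}

#' @export
print.clustering_score <- function(x, ...) {
  cat(sprintf(
    "<clustering_score> %.4g (gap %.4g / spreads %.4g + %.4g)\n",
    x$score, x$gap, x$spread_case, x$spread_control
  ))
  invisible(x)
}

#' Default selection-parameter grid
#'
#' Spans p-rank depth, ROC-importance floor and correlation ceiling while
#' holding the minimum methylation difference at 5%.
#'
#' @return List of [selection_params()] combinations.
#' @export
default_grid <- function() {
  combos <- expand.grid(top_n = c(100L, 200L, 300L, 500L, 1000L),
                        auc_min = c(0.75, 0.85, 0.95),
                        r_max = c(0.7, 0.8, 0.9),
                        KEEP.OUT.ATTRS = FALSE)
  purrr::pmap(combos, function(top_n, auc_min, r_max) {
    selection_params(delta_min = 0.05, top_n = top_n,
                     auc_min = auc_min, r_max = r_max)
  })
}

param_tuple <- function(p) c(p$delta_min, p$top_n, p$auc_min, p$r_max)

# strict lexicographic less-than on parameter tuples
tuple_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Grid search for the best-clustering signature profile
#'
#' Evaluates [select_probes()] plus [clustering_score()] for every parameter
#' combination and returns the profile with the highest score. Ties break
#' deterministically: fewer probes first, then the lexicographically smaller
#' parameter tuple `(delta_min, top_n, auc_min, r_max)`. Combinations that
#' select no probes are skipped and recorded.
#'
#' @param table Differential methylation tibble (`auc` may be unpopulated;
#'   it is filled here for the probes that can matter).
#' @param beta Beta matrix restricted to the training samples.
#' @param labels Named `"case"`/`"control"` vector.
#' @param grid List of [selection_params()] (default [default_grid()]).
#' @return A `signature_profile`: `probe_ids`, `params`, `score`
#'   (a `clustering_score`), `hypo_fraction` (fraction of selected probes
#'   with negative `delta_beta`), `n_skipped`, `n_evaluated`.
#' @export
grid_search <- function(table, beta, labels, grid = default_grid()) {
  if (length(grid) == 0) abort("`grid` must be nonempty.")
  delta_floor <- min(vapply(grid, `[[`, numeric(1), "delta_min"))
  cand_ids <- table$probe_id[abs(table$delta_beta) >= delta_floor]
  if (length(cand_ids) > 0 && any(is.na(table$auc[match(cand_ids,
                                                        table$probe_id)]))) {
    auc <- probe_auc_matrix(beta[cand_ids, , drop = FALSE], labels)
    table$auc[match(cand_ids, table$probe_id)] <- unname(auc)
  }

  best <- NULL
  n_skipped <- 0L
  for (params in grid) {
    probes <- tryCatch(
      select_probes(table, beta, params),
      episig_no_candidates = function(e) character(0)
    )
    if (length(probes) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    sc <- clustering_score(beta, probes, labels)
    challenger <- list(probes = probes, params = params, score = sc)
    if (is.null(best) ||
        sc$score > best$score$score ||
        (sc$score == best$score$score &&
           (length(probes) < length(best$probes) ||
              (length(probes) == length(best$probes) &&
                 tuple_less(param_tuple(params),
                            param_tuple(best$params)))))) {
      best <- challenger
    }
  }
  if (is.null(best)) {
    abort("Every parameter combination selected an empty probe set.",
          class = "episig_empty_grid")
  }
  sel <- table[match(best$probes, table$probe_id), ]
  structure(
    list(probe_ids = best$probes,
         params = best$params,
         score = best$score,
         hypo_fraction = mean(sel$delta_beta < 0),
         n_skipped = n_skipped,
         n_evaluated = length(grid) - n_skipped),
    class = "signature_profile"
  )
}

#' @export
print.signature_profile <- function(x, ...) {
  cat(sprintf(
    "<signature_profile> %d probes (%.0f%% hypomethylated), score %.3g\n",
    length(x$probe_ids), 100 * x$hypo_fraction, x$score$score
  ))
  cat(sprintf("  params: delta_min %.2f, top_n %d, auc_min %.2f, r_max %.2f\n",
              x$params$delta_min, x$params$top_n, x$params$auc_min,
              x$params$r_max))
  invisible(x)
}

#' @rdname grid_search
#' @param x A `signature_profile`.
#' @param ... Unused.
#' @export
glance.signature_profile <- function(x, ...) {
  tibble(
    n_probes = length(x$probe_ids),
    hypo_fraction = x$hypo_fraction,
    score = x$score$score,
    gap = x$score$gap,
    spread_case = x$score$spread_case,
    spread_control = x$score$spread_control,
    delta_min = x$params$delta_min,
    top_n = x$params$top_n,
    auc_min = x$params$auc_min,
    r_max = x$params$r_max
  )
}

#' Hierarchical clustering and MDS of labelled samples
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances) and
#' classical (Torgerson) multidimensional scaling to two dimensions over the
#' samples, restricted to the given probes. Purity is the fraction of
#' samples whose group label is the majority label of their side of the
#' two-cluster dendrogram cut.
#'
#' @param beta Beta matrix containing the labelled samples.
#' @param probes Nonempty probe id vector.
#' @param labels Named group vector over >= 3 samples.
#' @return A `meth_clustering` list: `hclust`, `mds` (tibble `sample_id`,
#'   `mds1`, `mds2`, `group`, `cluster`), `purity`.
#' @export
evaluate_clustering <- function(beta, probes, labels) {
  if (length(probes) == 0) abort("`probes` must be nonempty.")
  ids <- names(labels)
  if (length(ids) < 3) abort("MDS needs at least 3 samples.")
  X <- t(beta[probes, ids, drop = FALSE])
  d <- dist(X)
  hc <- hclust(d, method = "ward.D2")
  k2 <- cutree(hc, k = 2)
  purity <- mean(vapply(seq_along(ids), function(i) {
    side <- names(which.max(table(labels[k2 == k2[i]])))
    labels[i] == side
  }, logical(1)))
  mds <- cmdscale(d, k = 2)
  structure(
    list(hclust = hc,
         mds = tibble(sample_id = ids,
                      mds1 = mds[, 1], mds2 = mds[, 2],
                      group = unname(labels), cluster = unname(k2)),
         purity = purity),
    class = "meth_clustering"
  )
}

#' @export
print.meth_clustering <- function(x, ...) {
  cat(sprintf("<meth_clustering> %d samples, 2-cut purity %.3f\n",
              nrow(x$mds), x$purity))
  invisible(x)
}
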