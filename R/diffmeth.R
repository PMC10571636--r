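#' Build the per-probe design matrix
#'
#' Intercept, case indicator (case = 1), and the blood-cell-proportion
#' covariates with the first (reference) cell type dropped — the proportions
#' are compositional, so one column is collinear with the intercept.
#'
#' @param sheet Sample-sheet tibble containing the training samples, with a
#'   `cell_*` column per cell type.
#' @param labels Named character vector (`"case"`/`"control"`) over the
#'   training sample ids, e.g. from [match_labels()].
#' @return Numeric design matrix, one row per label entry, in label order.
#' @export
build_design <- function(sheet, labels) {
  ids <- names(labels)
  missing <- setdiff(ids, sheet$sample_id)
  if (length(missing) > 0) {
    abort(paste0("Samples absent from the sheet: ",
                 paste(missing, collapse = ", ")))
  }
  rows <- sheet[match(ids, sheet$sample_id), ]
  cells <- cell_prop_cols(rows)
  covars <- if (length(cells) > 1) {
    as.matrix(rows[, cells[-1], drop = FALSE])
  } else {
    matrix(0, nrow(rows), 0)
  }
  X <- cbind(intercept = 1,
             group = as.numeric(labels == "case"),
             covars)
  rownames(X) <- ids
  X
}

#' Per-probe ordinary least squares on M-values
#'
#' Fits `M ~ design` independently for every probe and extracts the group
#' (case vs control) coefficient, its unscaled standard error factor
#' `sqrt(v_g)` (the group diagonal entry of `(X'X)^-1`), the residual mean
#' square, and the residual degrees of freedom.
#'
#' @param m M-value matrix, probes x samples.
#' @param design Design matrix from [build_design()]; rows must match the
#'   columns of `m` in order.
#' @return Tibble: `probe_id`, `coef`, `se` (unscaled), `s_sq`, `df_resid`.
#' @export
fit_linear_models <- function(m, design) {
  assert_beta_matrix(m, "m")
  if (nrow(design) != ncol(m)) {
    abort("`design` rows must equal the number of samples in `m`.")
  }
  if (!all(is.finite(m))) abort("`m` contains non-finite values.")
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    abort("Design matrix is rank-deficient; drop collinear covariates.")
  }
  df_resid <- nrow(design) - qrX$rank
  if (df_resid < 1) abort("No residual degrees of freedom.")

  Y <- t(m)                                  # samples x probes
  coefs <- qr.coef(qrX, Y)                   # k x probes
  resid <- qr.resid(qrX, Y)
  s_sq <- colSums(resid^2) / df_resid
  xtx_inv <- chol2inv(chol(crossprod(design)))
  grp <- match("group", colnames(design))
  v_g <- xtx_inv[grp, grp]

  tibble(
    probe_id = rownames(m),
    coef = unname(coefs[grp, ]),
    se = sqrt(v_g),
    s_sq = as.numeric(s_sq),
    df_resid = df_resid
  )
}

# Invert the trigamma function by bisection on (0, 1e7] to `tol`.
trigamma_inverse <- function(y, tol = 1e-8) {
  vapply(y, function(yy) {
    if (yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))      # psi'(x) ~ 1/x^2 + ... as x -> 0
    lo <- 1e-8
    hi <- 1e8
    # trigamma is strictly decreasing: psi'(lo) huge, psi'(hi) tiny
    repeat {
      mid <- (lo + hi) / 2
      if (trigamma(mid) > yy) lo <- mid else hi <- mid
      if (hi - lo < tol * max(1, lo)) break
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Estimate the empirical-Bayes variance prior
#'
#' Matches moments of `log(s_g^2)` to its theoretical distribution under
#' `s_g^2 ~ s0^2 * F(d_g, d0)`: with
#' `e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)`, the excess of `var(e)`
#' over the sampling-only expectation `mean(trigamma(d_g/2))` determines
#' `d0` through a trigamma inversion, and `mean(e)` then determines `s0^2`.
#' When the observed spread does not exceed the sampling expectation the
#' prior is degenerate: `d0 = Inf` and `s0^2 = mean(s_g^2)`.
#'
#' @param s_sq Per-probe residual variances (at least 10 positive values).
#' @param df_resid Residual degrees of freedom (scalar or per-probe).
#' @return An `ebayes_prior` list with `d0` and `s0_sq`.
#' @export
estimate_prior <- function(s_sq, df_resid) {
  df <- rep_len(df_resid, length(s_sq))
  ok <- is.finite(s_sq) & s_sq > 0 & df > 0
  if (sum(ok) < 10) {
    abort("Need at least 10 probes with positive residual variance.")
  }
  x <- s_sq[ok]
  df <- df[ok]
  z <- log(x)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- mean(x)
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "ebayes_prior")
}

#' @export
print.ebayes_prior <- function(x, ...) {
  cat(sprintf("<ebayes_prior> d0 = %s, s0_sq = %.6g\n",
              format(x$d0), x$s0_sq))
  invisible(x)
}

#' Moderated t-statistics and p-values
#'
#' Shrinks each probe's residual variance toward the prior,
#' `s2_post = (d0 * s0_sq + d_g * s_g^2) / (d0 + d_g)` (the limit `s0_sq`
#' when `d0` is infinite), forms `t = coef / (se * sqrt(s2_post))`, and
#' computes two-sided p-values from the t distribution on `d_g + d0` degrees
#' of freedom (standard normal when `d0 = Inf`). `d0 = 0` recovers the
#' ordinary t-test.
#'
#' @param stats Tibble from [fit_linear_models()].
#' @param prior An `ebayes_prior` (or list with `d0`, `s0_sq`).
#' @return `stats` with columns `t_mod` and `p` added.
#' @export
moderate <- function(stats, prior) {
  d0 <- prior$d0
  s0 <- prior$s0_sq
  if (is.na(d0) || d0 < 0 || !is.finite(s0) || s0 <= 0) {
    abort("Invalid prior: need d0 >= 0 and s0_sq > 0.")
  }
  if (any(stats$se == 0)) {
    abort("Zero unscaled standard error: degenerate design for some probe.")
  }
  dg <- stats$df_resid
  s2_post <- if (is.infinite(d0)) {
    rep_len(s0, nrow(stats))
  } else {
    (d0 * s0 + dg * stats$s_sq) / (d0 + dg)
  }
  t_mod <- stats$coef / (stats$se * sqrt(s2_post))
  df_total <- dg + d0
  p <- ifelse(is.infinite(df_total),
              2 * pnorm(-abs(t_mod)),
              2 * pt(-abs(t_mod), df = df_total))
  dplyr::mutate(stats, t_mod = t_mod, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: sort ascending, scale the i-th
#' smallest by `n/i`, take the running minimum from the top rank down, cap
#' at 1, and restore input order. Delegates to [stats::p.adjust()] after
#' validating the input.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Beta-scale methylation differences
#'
#' Per-probe `mean(case beta) - mean(control beta)`; negative values mark
#' hypomethylation in cases.
#'
#' @param beta Beta matrix, probes x samples.
#' @param labels Named `"case"`/`"control"` vector over (a subset of) the
#'   matrix's samples.
#' @return Tibble: `probe_id`, `delta_beta`.
#' @export
delta_beta <- function(beta, labels) {
  assert_beta_matrix(beta)
  ids <- names(labels)
  missing <- setdiff(ids, colnames(beta))
  if (length(missing) > 0) {
    abort(paste0("Samples absent from the beta matrix: ",
                 paste(missing, collapse = ", ")))
  }
  case_ids <- ids[labels == "case"]
  ctrl_ids <- ids[labels == "control"]
  if (length(case_ids) == 0 || length(ctrl_ids) == 0) {
    abort("Both groups must be nonempty.")
  }
  tibble(
    probe_id = rownames(beta),
    delta_beta = unname(rowMeans(beta[, case_ids, drop = FALSE]) -
                          rowMeans(beta[, ctrl_ids, drop = FALSE]))
  )
}

#' Full per-probe differential methylation analysis
#'
#' Chains [fit_linear_models()], [estimate_prior()], [moderate()],
#' [bh_adjust()] and [delta_beta()] into a single fitted object.
#'
#' @param beta Filtered beta matrix (probes x samples, training samples
#'   included among the columns).
#' @param sheet Sample sheet covering the training samples.
#' @param labels Named `"case"`/`"control"` vector, e.g. [match_labels()].
#' @param eps Offset for the beta-to-M transform.
#' @return A `diffmeth_fit`: list with `table` (tibble `probe_id`,
#'   `delta_beta`, `coef`, `se`, `s_sq`, `df_resid`, `t_mod`, `p`, `p_adj`,
#'   `auc` — `auc` is `NA` until filled by [add_probe_importance()]),
#'   `prior`, `labels`.
#' @export
diff_methylation <- function(beta, sheet, labels, eps = 0.01) {
  ids <- names(labels)
  m <- beta_to_m(beta[, ids, drop = FALSE], eps = eps)
  design <- build_design(sheet, labels)
  fit <- fit_linear_models(m, design)
  prior <- estimate_prior(fit$s_sq, fit$df_resid)
  fit <- moderate(fit, prior)
  fit$p_adj <- bh_adjust(fit$p)
  db <- delta_beta(beta, labels)
  table <- dplyr::left_join(db, fit, by = "probe_id") |>
    dplyr::mutate(auc = NA_real_) |>
    dplyr::relocate("probe_id", "delta_beta", "coef", "se", "s_sq",
                    "df_resid", "t_mod", "p", "p_adj", "auc")
  structure(list(table = table, prior = prior, labels = labels),
            class = "diffmeth_fit")
}

#' @export
print.diffmeth_fit <- function(x, ...) {
  cat(sprintf("<diffmeth_fit> %d probes, %d cases vs %d controls\n",
              nrow(x$table), sum(x$labels == "case"),
              sum(x$labels == "control")))
  cat(sprintf("  prior: d0 = %s, s0_sq = %.4g; %d probes at FDR < 0.05\n",
              format(x$prior$d0), x$prior$s0_sq,
              sum(x$table$p_adj < 0.05)))
  invisible(x)
}

#' @rdname diff_methylation
#' @param x A `diffmeth_fit`.
#' @param ... Unused.
#' @export
tidy.diffmeth_fit <- function(x, ...) x$table

#' @rdname diff_methylation
#' @export
glance.diffmeth_fit <- function(x, ...) {
  tibble(
    n_probes = nrow(x$table),
    n_cases = sum(x$labels == "case"),
    n_controls = sum(x$labels == "control"),
    d0 = x$prior$d0,
    s0_sq = x$prior$s0_sq,
    n_fdr_05 = sum(x$table$p_adj < 0.05)
  )
}
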