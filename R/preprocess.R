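#' Remove samples with excessive detection failures
#'
#' A probe-sample measurement is called failed when its detection p-value
#' exceeds `detp_threshold`. Samples whose failed fraction is strictly
#' greater than `max_failed_fraction` (default 5%) are excluded; the
#' remaining sample order is preserved.
#'
#' @param beta Numeric probes x samples beta matrix with dimnames.
#' @param detp Detection p-value matrix on the same axes.
#' @param max_failed_fraction Maximum tolerated fraction of failed probes
#'   per sample.
#' @param detp_threshold Detection p-value above which a measurement is
#'   failed.
#' @return The beta matrix restricted to retained samples, with attribute
#'   `removed_samples` naming the excluded ones.
#' @export
#' @examples
#' sim <- generate_dataset(sim_config(n_probes = 100, n_cases = 3,
#'                                    n_controls = 9, n_heldout = 0,
#'                                    n_replicates = 0, n_signature = 0,
#'                                    seed = 2))
#' kept <- filter_samples(sim$beta, sim$detp)
filter_samples <- function(beta, detp, max_failed_fraction = 0.05,
                           detp_threshold = 0.01) {
  assert_beta_matrix(beta)
  assert_same_axes(beta, detp)
  assert_fraction(max_failed_fraction, "max_failed_fraction")
  failed_frac <- colMeans(detp > detp_threshold)
  keep <- failed_frac <= max_failed_fraction
  if (!any(keep)) {
    abort(sprintf(
      "All samples exceed the %.1f%% failed-probe threshold.",
      100 * max_failed_fraction
    ))
  }
  out <- beta[, keep, drop = FALSE]
  attr(out, "removed_samples") <- colnames(beta)[!keep]
  out
}

#' Filter probes by detection, chromosome, and exclusion flags
#'
#' Applies the four standard probe exclusions: (i) detection failure
#' (p > `detp_threshold`) in any retained sample, (ii) location on the X or Y
#' chromosome, (iii) cross-reactive probes, (iv) probes targeting CpG sites
#' that overlap SNPs. The result is the intersection of all four filters.
#'
#' @inheritParams filter_samples
#' @param manifest Probe manifest tibble with columns `probe_id`,
#'   `chromosome`, `cross_reactive`, `snp_overlap`.
#' @param detp_threshold Detection p-value failure cutoff (default 0.01).
#' @return Filtered beta matrix with attribute `filter_report`, a named list
#'   of per-criterion removal counts (a probe failing several criteria is
#'   counted under each).
#' @export
filter_probes <- function(beta, manifest, detp, detp_threshold = 0.01) {
  assert_beta_matrix(beta)
  probes <- rownames(beta)
  missing <- setdiff(probes, manifest$probe_id)
  if (length(missing) > 0) {
    abort(paste0("Probes absent from the manifest: ",
                 paste(utils::head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) sprintf(" (+%d more)",
                                                  length(missing) - 5)))
  }
  missing_detp <- setdiff(probes, rownames(detp))
  if (length(missing_detp) > 0 ||
      !all(colnames(beta) %in% colnames(detp))) {
    abort("`detp` must cover every probe and retained sample of `beta`.")
  }
  detp <- detp[probes, colnames(beta), drop = FALSE]
  man <- manifest[match(probes, manifest$probe_id), ]

  fail_det <- rowSums(detp > detp_threshold) > 0
  on_xy <- man$chromosome %in% c("chrX", "chrY", "X", "Y")
  cross <- as.logical(man$cross_reactive)
  snp <- as.logical(man$snp_overlap)

  keep <- !(fail_det | on_xy | cross | snp)
  out <- beta[keep, , drop = FALSE]
  attr(out, "filter_report") <- list(
    failed_detection = sum(fail_det),
    xy_chromosome = sum(on_xy),
    cross_reactive = sum(cross),
    snp_overlap = sum(snp),
    retained = sum(keep)
  )
  out
}

#' Convert beta values to M-values
#'
#' `M = log2((beta + eps) / (1 - beta + eps))`. The offset `eps` keeps M
#' finite over the closed interval `[0, 1]`; `M(0.5) = 0` for any `eps`.
#'
#' @param beta Beta matrix (or vector) of methylation fractions in `[0, 1]`.
#' @param eps Positive clamp constant (default 0.01).
#' @return Object of the same shape on the M scale.
#' @export
#' @examples
#' beta_to_m(c(0.1, 0.5, 0.9))
beta_to_m <- function(beta, eps = 0.01) {
  if (eps <= 0) abort("`eps` must be positive.")
  log2((beta + eps) / (1 - beta + eps))
}

#' Convert M-values back to beta values
#'
#' Exact inverse of [beta_to_m()] for the same `eps`.
#' @param m M-value matrix or vector.
#' @inheritParams beta_to_m
#' @return Object of the same shape on the beta scale.
#' @export
m_to_beta <- function(m, eps = 0.01) {
  e <- 2^m
  (e * (1 + eps) - eps) / (1 + e)
}
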