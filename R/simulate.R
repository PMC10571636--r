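#' Simulation settings for Infinium-like methylation data
#'
#' Collects every knob of the synthetic-data generator into a validated
#' configuration object. Defaults describe a small rare-disorder discovery
#' cohort: 12 cases against a pool of 60 sex/array-matched controls on a
#' 20,000-probe array, with 200 signature probes hypomethylated in cases by
#' an absolute beta difference of 5-16%.
#'
#' @param n_probes Number of array probes.
#' @param n_cases Number of affected (case) individuals.
#' @param n_controls Size of the unaffected control pool.
#' @param n_heldout Number of affected test samples excluded from discovery.
#' @param n_replicates Number of lymphoblastoid (LB-line) technical
#'   replicates, one per case starting from the first.
#' @param n_signature Number of truly differentially methylated probes.
#' @param delta_range Length-2 interval for the absolute per-probe case
#'   effect on the beta scale (default `c(0.05, 0.16)`).
#' @param hypo_fraction Probability that a signature probe is hypomethylated
#'   (case minus control negative); 1 yields a fully hypomethylated profile.
#' @param noise_sd Per probe-sample Gaussian noise SD on the M scale.
#' @param n_cell_types Number of blood cell types whose proportions act as
#'   covariates.
#' @param cell_effect_sd SD of the per-probe, per-cell-type M-scale
#'   coefficients.
#' @param frac_xy,frac_cross_reactive,frac_snp Fractions of probes placed on
#'   X/Y chromosomes, flagged cross-reactive, or flagged as overlapping SNPs.
#' @param frac_failed_detection Fraction of probe-sample measurements given a
#'   failed (high) detection p-value.
#' @param age_range Length-2 range of ages in years.
#' @param sex_ratio Probability that an individual is male.
#' @param array_types Character vector of array platforms to sample from.
#' @param seed Integer seed; a fixed seed makes the full output reproducible.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_probes = 500, n_signature = 10, seed = 7)
sim_config <- function(n_probes = 20000,
                       n_cases = 12,
                       n_controls = 60,
                       n_heldout = 2,
                       n_replicates = 3,
                       n_signature = 200,
                       delta_range = c(0.05, 0.16),
                       hypo_fraction = 1,
                       noise_sd = 0.25,
                       n_cell_types = 6,
                       cell_effect_sd = 0.5,
                       frac_xy = 0.05,
                       frac_cross_reactive = 0.03,
                       frac_snp = 0.03,
                       frac_failed_detection = 0.001,
                       age_range = c(2, 48),
                       sex_ratio = 0.75,
                       array_types = c("450k", "EPIC"),
                       seed = 1) {
  cfg <- list(
    n_probes = n_probes, n_cases = n_cases, n_controls = n_controls,
    n_heldout = n_heldout, n_replicates = n_replicates,
    n_signature = n_signature, delta_range = delta_range,
    hypo_fraction = hypo_fraction, noise_sd = noise_sd,
    n_cell_types = n_cell_types, cell_effect_sd = cell_effect_sd,
    frac_xy = frac_xy, frac_cross_reactive = frac_cross_reactive,
    frac_snp = frac_snp, frac_failed_detection = frac_failed_detection,
    age_range = age_range, sex_ratio = sex_ratio,
    array_types = array_types, seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_probes", "n_cases", "n_controls", "n_heldout",
              "n_replicates", "n_signature", "n_cell_types")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != floor(v)) {
      abort(sprintf("`%s` must be a single non-negative integer.", nm))
    }
  }
  if (cfg$n_probes < 1) abort("`n_probes` must be at least 1.")
  if (cfg$n_signature > cfg$n_probes) {
    abort("`n_signature` must not exceed `n_probes`.")
  }
  if (cfg$n_replicates > cfg$n_cases) {
    abort("`n_replicates` must not exceed `n_cases` (one replicate per case).")
  }
  for (nm in c("hypo_fraction", "frac_xy", "frac_cross_reactive", "frac_snp",
               "frac_failed_detection", "sex_ratio")) {
    assert_fraction(cfg[[nm]], nm)
  }
  dr <- cfg$delta_range
  if (length(dr) != 2 || dr[1] > dr[2] || dr[1] <= 0 || dr[2] >= 0.5) {
    abort("`delta_range` must be an increasing interval within (0, 0.5).")
  }
  if (cfg$noise_sd < 0 || cfg$cell_effect_sd < 0) {
    abort("`noise_sd` and `cell_effect_sd` must be non-negative.")
  }
  if (length(cfg$age_range) != 2 || cfg$age_range[1] > cfg$age_range[2]) {
    abort("`age_range` must be an increasing length-2 range.")
  }
  if (length(cfg$array_types) < 1) abort("`array_types` must be nonempty.")
  invisible(cfg)
}

# Blood-typical Dirichlet concentrations: neutrophil-dominated with smaller
# lymphoid and myeloid fractions, total concentration 40.
cell_type_alpha <- function(k) {
  if (k == 6) {
    base <- c(neutrophils = 0.55, cd4t = 0.15, cd8t = 0.10,
              bcell = 0.08, monocytes = 0.08, nk = 0.04)
  } else {
    w <- rev(seq_len(k))
    base <- setNames(w / sum(w), paste0("type", seq_len(k)))
  }
  40 * base
}

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

#' Generate a synthetic Infinium-like methylation dataset
#'
#' Draws a complete, seeded dataset with the statistical structure the
#' episignature workflow assumes: probe baselines from a three-component
#' bimodal-plus-intermediate mixture on the M scale; a signature probe subset
#' whose case effect is injected on the beta scale (clamped to `[0.01, 0.99]`)
#' so the configured effect sizes are directly interpretable as absolute
#' methylation differences; blood-cell-composition covariates and Gaussian
#' measurement noise added on the M scale; LB-line replicates that share their
#' source individual's expected methylation plus technical noise at half the
#' biological noise SD; and sporadic detection failures.
#'
#' Signature probes are drawn from clean (autosomal, unflagged) probes with
#' intermediate baselines (beta in `[0.25, 0.75]`), so the full configured
#' effect is realizable without clamping — mirroring the intermediate
#' methylation typical of differentially methylated positions.
#'
#' @param config A [sim_config()] object.
#'
#' @return A `meth_dataset` list with elements:
#' \describe{
#'   \item{beta}{numeric matrix, probes x samples, values in (0, 1)}
#'   \item{detp}{detection p-value matrix on the same axes}
#'   \item{manifest}{tibble: `probe_id`, `chromosome`, `position`,
#'     `cross_reactive`, `snp_overlap`}
#'   \item{samples}{tibble sample sheet: `sample_id`, `group`
#'     (case/control_pool/heldout), `sex`, `age`, `array_type`, `tissue`,
#'     `replicate_of`, and `cell_*` proportion columns}
#'   \item{truth}{list: `signature_probes`, named `true_delta` vector over all
#'     probes (beta scale), `cell_proportions` matrix, `replicate_map` tibble}
#'   \item{config}{the configuration used}
#' }
#' @export
#' @examples
#' sim <- generate_dataset(sim_config(n_probes = 300, n_signature = 10,
#'                                    n_cases = 6, n_controls = 18,
#'                                    n_heldout = 1, n_replicates = 1,
#'                                    seed = 11))
#' dim(sim$beta)
generate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  cfg <- config

  probe_ids <- sprintf("cg%08d", seq_len(cfg$n_probes))

  ## stage 1: manifest and baseline methylation -----------------------------
  set.seed(stage_seed(cfg$seed, 1))
  n_xy <- round(cfg$frac_xy * cfg$n_probes)
  chrom <- sample(paste0("chr", 1:22), cfg$n_probes, replace = TRUE)
  if (n_xy > 0) {
    xy_idx <- sample.int(cfg$n_probes, n_xy)
    chrom[xy_idx] <- sample(c("chrX", "chrY"), n_xy,
                            replace = TRUE, prob = c(0.8, 0.2))
  }
  manifest <- tibble(
    probe_id = probe_ids,
    chromosome = chrom,
    position = sample.int(1e8, cfg$n_probes, replace = TRUE),
    cross_reactive = runif(cfg$n_probes) < cfg$frac_cross_reactive,
    snp_overlap = runif(cfg$n_probes) < cfg$frac_snp
  )

  comp <- sample.int(3, cfg$n_probes, replace = TRUE,
                     prob = c(0.4, 0.2, 0.4))
  mu <- c(-3, 0, 3)[comp]
  sd0 <- c(0.9, 0.5, 0.9)[comp]
  m_baseline <- rnorm(cfg$n_probes, mu, sd0)
  beta_baseline <- expit2(m_baseline)

  ## stage 2: signature probes and true effects -----------------------------
  set.seed(stage_seed(cfg$seed, 2))
  true_delta <- setNames(numeric(cfg$n_probes), probe_ids)
  signature_probes <- character(0)
  if (cfg$n_signature > 0) {
    eligible <- which(
      !(manifest$chromosome %in% c("chrX", "chrY")) &
        !manifest$cross_reactive & !manifest$snp_overlap &
        beta_baseline >= 0.25 & beta_baseline <= 0.75
    )
    if (length(eligible) < cfg$n_signature) {
      abort(paste0(
        "Too few clean intermediate-methylation probes to host the ",
        "requested signature; increase `n_probes` or lower `n_signature`."
      ))
    }
    sig_idx <- sort(sample(eligible, cfg$n_signature))
    signature_probes <- probe_ids[sig_idx]
    mag <- runif(cfg$n_signature, cfg$delta_range[1], cfg$delta_range[2])
    sign <- ifelse(runif(cfg$n_signature) < cfg$hypo_fraction, -1, 1)
    true_delta[sig_idx] <- mag * sign
  }

  ## stage 3: sample sheet and cell proportions -----------------------------
  set.seed(stage_seed(cfg$seed, 3))
  case_ids <- sprintf("case%02d", seq_len(cfg$n_cases))
  ctrl_ids <- sprintf("ctrl%02d", seq_len(cfg$n_controls))
  test_ids <- sprintf("test%02d", seq_len(cfg$n_heldout))
  rep_ids <- sprintf("rep%02d", seq_len(cfg$n_replicates))

  draw_age <- function(n) runif(n, cfg$age_range[1], cfg$age_range[2])
  draw_sex <- function(n) c("F", "M")[1L + (runif(n) < cfg$sex_ratio)]
  draw_array <- function(n) sample(cfg$array_types, n, replace = TRUE)

  case_sex <- draw_sex(cfg$n_cases)
  case_age <- draw_age(cfg$n_cases)
  case_array <- draw_array(cfg$n_cases)

  # controls cycle over the cases, copying sex and array type and jittering
  # age, so exact-stratum matching is always feasible at the default ratio
  src <- if (cfg$n_controls > 0) {
    rep_len(seq_len(max(cfg$n_cases, 1)), cfg$n_controls)
  } else integer(0)
  ctrl_sex <- case_sex[src]
  ctrl_array <- case_array[src]
  ctrl_age <- pmin(pmax(case_age[src] + rnorm(cfg$n_controls, 0, 3),
                        cfg$age_range[1]), cfg$age_range[2])

  rep_src <- case_ids[seq_len(cfg$n_replicates)]

  samples <- dplyr::bind_rows(
    tibble(sample_id = case_ids, group = "case", sex = case_sex,
           age = case_age, array_type = case_array,
           tissue = "peripheral_blood", replicate_of = NA_character_),
    tibble(sample_id = ctrl_ids, group = "control_pool", sex = ctrl_sex,
           age = ctrl_age, array_type = ctrl_array,
           tissue = "peripheral_blood", replicate_of = NA_character_),
    tibble(sample_id = test_ids, group = "heldout",
           sex = draw_sex(cfg$n_heldout), age = draw_age(cfg$n_heldout),
           array_type = draw_array(cfg$n_heldout),
           tissue = "peripheral_blood", replicate_of = NA_character_),
    tibble(sample_id = rep_ids, group = "heldout",
           sex = case_sex[seq_len(cfg$n_replicates)],
           age = case_age[seq_len(cfg$n_replicates)],
           array_type = case_array[seq_len(cfg$n_replicates)],
           tissue = "LB_line", replicate_of = rep_src)
  )
  n_samples <- nrow(samples)

  alpha <- cell_type_alpha(cfg$n_cell_types)
  props <- rdirichlet(n_samples, alpha)
  rownames(props) <- samples$sample_id
  # replicates inherit their source individual's cell make-up
  if (cfg$n_replicates > 0) {
    props[rep_ids, ] <- props[rep_src, , drop = FALSE]
  }
  prop_tbl <- as_tibble(props)
  names(prop_tbl) <- paste0("cell_", colnames(props))
  samples <- dplyr::bind_cols(samples, prop_tbl)

  ## expected M per probe x sample ------------------------------------------
  affected <- samples$group %in% c("case", "heldout")  # carriers incl. tests
  beta_exp <- matrix(beta_baseline, cfg$n_probes, n_samples)
  if (cfg$n_signature > 0) {
    sig_idx <- match(signature_probes, probe_ids)
    beta_exp[sig_idx, affected] <- beta_exp[sig_idx, affected] +
      true_delta[sig_idx]
  }
  beta_exp <- pmin(pmax(beta_exp, 0.01), 0.99)
  m_exp <- logit2(beta_exp)

  cell_coef <- matrix(rnorm(cfg$n_probes * cfg$n_cell_types,
                            0, cfg$cell_effect_sd),
                      cfg$n_probes, cfg$n_cell_types)
  props_centered <- sweep(props, 2, alpha / sum(alpha))
  m_exp <- m_exp + cell_coef %*% t(props_centered)

  ## stage 4: measurement noise ---------------------------------------------
  set.seed(stage_seed(cfg$seed, 4))
  noise <- matrix(rnorm(cfg$n_probes * n_samples, 0, cfg$noise_sd),
                  cfg$n_probes, n_samples)
  rep_cols <- match(rep_ids, samples$sample_id)
  if (length(rep_cols) > 0) {
    # technical-only noise at half SD; expected values already equal the
    # source individual's (same covariates, same true effects)
    noise[, rep_cols] <- matrix(
      rnorm(cfg$n_probes * length(rep_cols), 0, cfg$noise_sd / 2),
      cfg$n_probes, length(rep_cols)
    )
  }
  m_obs <- m_exp + noise
  beta <- expit2(m_obs)
  dimnames(beta) <- list(probe_ids, samples$sample_id)

  ## stage 5: detection p-values --------------------------------------------
  set.seed(stage_seed(cfg$seed, 5))
  detp <- matrix(runif(cfg$n_probes * n_samples, 0, 0.005),
                 cfg$n_probes, n_samples,
                 dimnames = dimnames(beta))
  n_fail <- round(cfg$frac_failed_detection * length(detp))
  if (n_fail > 0) {
    fail_at <- sample.int(length(detp), n_fail)
    detp[fail_at] <- runif(n_fail, 0.02, 1)
  }

  truth <- list(
    signature_probes = signature_probes,
    true_delta = true_delta,
    cell_proportions = props,
    replicate_map = tibble(replicate_id = rep_ids, source_id = rep_src)
  )

  structure(
    list(beta = beta, detp = detp, manifest = manifest, samples = samples,
         truth = truth, config = cfg),
    class = "meth_dataset"
  )
}

#' @export
print.meth_dataset <- function(x, ...) {
  cat("<meth_dataset>\n")
  cat(sprintf("  %d probes x %d samples (%d signature probes)\n",
              nrow(x$beta), ncol(x$beta),
              length(x$truth$signature_probes)))
  grp <- table(x$samples$group)
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
      "\n")
  invisible(x)
}

# Printed per-feature penetrance counts for the 40-individual cohort:
# affected / assessed; individuals beyond `assessed` are recorded unknown.
phenotype_feature_counts <- function() {
  tibble::tribble(
    ~feature,                 ~n_affected, ~n_assessed,
    "id_dd",                  31L,         39L,
    "speech_delay_regression", 34L,        40L,
    "macrocephaly_overgrowth", 17L,        38L,
    "motor_delay",            25L,         39L,
    "seizures_epilepsy",       9L,         38L,
    "hypotonia",              16L,         38L,
    "behavioral_difficulties", 23L,        40L,
    "dysmorphic_features",    23L,         40L,
    "increased_height",       10L,         34L,
    "increased_weight",       10L,         32L
  )
}

#' Fixed clinical feature vocabulary
#'
#' The feature names recognised by [summarize_penetrance()].
#' @return Character vector of feature names.
#' @export
phenotype_features <- function() phenotype_feature_counts()$feature

#' Clinical phenotype fixture for the 40-individual cohort
#'
#' Builds the per-individual phenotype table whose per-feature
#' affected/assessed counts equal the cohort's published penetrance counts
#' (e.g. intellectual disability or developmental delay in 31 of 39 assessed
#' individuals). Individual identities are synthetic: statuses are assigned
#' in id order (affected first, then unaffected, then unassessed), which
#' fixes the marginal counts without asserting real per-individual data.
#'
#' @return A tibble with columns `individual_id`, `feature`, `status`
#'   (`yes`/`no`/`unknown`), 40 individuals x 10 features.
#' @export
#' @examples
#' pheno <- generate_phenotype_fixture()
#' summarize_penetrance(pheno)
generate_phenotype_fixture <- function() {
  counts <- phenotype_feature_counts()
  ids <- sprintf("ind%02d", 1:40)
  purrr::pmap_dfr(counts, function(feature, n_affected, n_assessed) {
    status <- rep("unknown", 40L)
    status[seq_len(n_assessed)] <- "no"
    status[seq_len(n_affected)] <- "yes"
    tibble(individual_id = ids, feature = feature, status = status)
  })
}
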