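# Internal helpers shared across modules.

# Deterministic per-stage substream seeds derived from one global seed, so
# adding draws to one generation stage never perturbs another.
stage_seed <- function(seed, stage) {
  (as.double(seed) * 48271 + stage * 2654435) %% 2147483647
}

# logit2 on the open interval; the user-facing clamped version is beta_to_m().
logit2 <- function(beta) log2(beta / (1 - beta))

expit2 <- function(m) {
  e <- 2^m
  e / (1 + e)
}

assert_beta_matrix <- function(beta, arg = "beta") {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    abort(sprintf("`%s` must be a numeric matrix (probes x samples).", arg))
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    abort(sprintf("`%s` must have probe rownames and sample colnames.", arg))
  }
  if (anyDuplicated(rownames(beta)) || anyDuplicated(colnames(beta))) {
    abort(sprintf("`%s` has duplicated probe or sample ids.", arg))
  }
  invisible(beta)
}

assert_same_axes <- function(a, b, args = c("beta", "detp")) {
  if (!identical(dim(a), dim(b)) ||
      !identical(rownames(a), rownames(b)) ||
      !identical(colnames(a), colnames(b))) {
    abort(sprintf("`%s` and `%s` must share identical probe and sample axes.",
                  args[1], args[2]))
  }
  invisible(NULL)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1].", name))
  }
  invisible(x)
}

cell_prop_cols <- function(sheet) {
  grep("^cell_", names(sheet), value = TRUE)
}

# round half away from zero to the nearest integer (base round() is
# half-to-even, which does not reproduce e.g. 57.5 -> 58)
round_half_up <- function(x) floor(x + 0.5)
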