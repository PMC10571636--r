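# Shared fixture builders: everything is generated in code at test time.

tiny_config <- function(...) {
  defaults <- list(n_probes = 400, n_cases = 6, n_controls = 24,
                   n_heldout = 1, n_replicates = 1, n_signature = 20,
                   noise_sd = 0.2, seed = 101)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# A small beta matrix with explicit values, probes x samples.
toy_beta <- function(values, probes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- probes %||% sprintf("p%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Manifest in which every probe is clean and autosomal unless overridden.
clean_manifest <- function(probe_ids, chromosome = "chr1",
                           cross_reactive = FALSE, snp_overlap = FALSE) {
  tibble::tibble(
    probe_id = probe_ids,
    chromosome = rep_len(chromosome, length(probe_ids)),
    position = seq_along(probe_ids) * 1000L,
    cross_reactive = rep_len(cross_reactive, length(probe_ids)),
    snp_overlap = rep_len(snp_overlap, length(probe_ids))
  )
}

# Named case/control label vector for columns of a beta matrix.
toy_labels <- function(beta, n_case) {
  ids <- colnames(beta)
  stats::setNames(
    c(rep("case", n_case), rep("control", length(ids) - n_case)),
    ids
  )
}
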