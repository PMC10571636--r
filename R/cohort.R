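#' Summarize clinical penetrance per feature
#'
#' Counts affected (`yes`) against assessed (`yes` + `no`) individuals for
#' each clinical feature and reports the penetrance as an integer percent,
#' rounded half-up (so 23/40 prints 58). Features with no assessed
#' individuals are flagged not computable rather than reported as zero.
#'
#' @param table Phenotype tibble with columns `individual_id`, `feature`,
#'   `status` (`yes` / `no` / `unknown`); features must belong to
#'   [phenotype_features()].
#' @return Tibble: `feature`, `n_affected`, `n_assessed`, `percent`
#'   (`NA` when not computable), `computable`.
#' @export
#' @examples
#' summarize_penetrance(generate_phenotype_fixture())
summarize_penetrance <- function(table) {
  needed <- c("individual_id", "feature", "status")
  if (!all(needed %in% names(table))) {
    abort(paste0("Phenotype table must contain columns: ",
                 paste(needed, collapse = ", ")))
  }
  bad_status <- setdiff(unique(table$status), c("yes", "no", "unknown"))
  if (length(bad_status) > 0) {
    abort(paste0("Invalid status values: ",
                 paste(bad_status, collapse = ", ")))
  }
  bad_feat <- setdiff(unique(table$feature), phenotype_features())
  if (length(bad_feat) > 0) {
    abort(paste0("Unknown clinical features: ",
                 paste(bad_feat, collapse = ", ")))
  }
  if (anyDuplicated(table[c("individual_id", "feature")])) {
    abort("Each (individual, feature) pair must appear once.")
  }
  table |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      n_affected = sum(.data$status == "yes"),
      n_assessed = sum(.data$status != "unknown"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      computable = .data$n_assessed > 0,
      percent = dplyr::if_else(
        .data$computable,
        round_half_up(100 * .data$n_affected / .data$n_assessed),
        NA_real_
      )
    ) |>
    dplyr::relocate("feature", "n_affected", "n_assessed", "percent",
                    "computable")
}
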