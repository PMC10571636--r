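#' Select matched unaffected controls for each case
#'
#' Controls are matched exactly on sex and array type; within each exact
#' stratum, each case (processed in sample-sheet order) greedily takes the
#' `ratio` controls nearest in age, without replacement. Age-distance ties
#' break by lexicographic sample id, making the result deterministic and
#' invariant to control-pool row order when ages are distinct.
#'
#' @param sheet Sample-sheet tibble with columns `sample_id`, `group`
#'   (`case` / `control_pool` / `heldout`), `sex`, `age`, `array_type`.
#' @param ratio Integer controls per case, between 3 and 8 — the
#'   conventional range for matched methylation discovery cohorts.
#' @return A `match_result` list: `matches` (tibble `case_id`, `control_id`,
#'   `age_distance`, ordered by case then increasing distance), `ratio`, and
#'   `summary` (per-case age-distance statistics tibble).
#' @export
#' @examples
#' sim <- generate_dataset(sim_config(n_probes = 50, n_cases = 4,
#'                                    n_controls = 20, n_heldout = 0,
#'                                    n_replicates = 0, n_signature = 0,
#'                                    seed = 3))
#' mr <- select_controls(sim$samples, ratio = 4)
#' mr$summary
select_controls <- function(sheet, ratio = 5) {
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio != floor(ratio) ||
      ratio < 3 || ratio > 8) {
    abort("`ratio` must be an integer between 3 and 8 controls per case.")
  }
  needed <- c("sample_id", "group", "sex", "age", "array_type")
  if (!all(needed %in% names(sheet))) {
    abort(paste0("Sample sheet must contain columns: ",
                 paste(needed, collapse = ", ")))
  }
  cases <- sheet[sheet$group == "case", ]
  pool <- sheet[sheet$group == "control_pool", ]
  if (nrow(pool) == 0) abort("Control pool is empty.")
  if (nrow(cases) == 0) abort("No case samples in the sheet.")

  available <- rep(TRUE, nrow(pool))
  rows <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    elig <- which(available &
                    pool$sex == cs$sex &
                    pool$array_type == cs$array_type)
    if (length(elig) < ratio) {
      abort(sprintf(
        "Case %s (sex %s, array %s): only %d eligible controls for ratio %d.",
        cs$sample_id, cs$sex, cs$array_type, length(elig), ratio
      ))
    }
    d <- abs(pool$age[elig] - cs$age)
    ord <- order(d, pool$sample_id[elig])
    take <- elig[ord[seq_len(ratio)]]
    available[take] <- FALSE
    rows[[i]] <- tibble(
      case_id = cs$sample_id,
      control_id = pool$sample_id[take],
      age_distance = abs(pool$age[take] - cs$age)
    )
  }
  matches <- dplyr::bind_rows(rows)
  summary <- matches |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(
      n_controls = dplyr::n(),
      mean_age_distance = mean(.data$age_distance),
      max_age_distance = max(.data$age_distance),
      .groups = "drop"
    )
  structure(
    list(matches = matches, ratio = as.integer(ratio), summary = summary),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d cases x %d controls each (1:%d)\n",
              nrow(x$summary), x$ratio, x$ratio))
  cat(sprintf("  mean age distance %.2f years\n",
              mean(x$matches$age_distance)))
  invisible(x)
}

#' Training labels from a match result
#'
#' Convenience accessor: the case and matched-control sample ids as a named
#' group factor, in case-then-control order, for downstream model fitting.
#'
#' @param match A `match_result` from [select_controls()].
#' @return Named character vector: values `"case"`/`"control"`, names sample
#'   ids.
#' @export
match_labels <- function(match) {
  stopifnot(inherits(match, "match_result"))
  cases <- unique(match$matches$case_id)
  ctrls <- match$matches$control_id
  setNames(c(rep("case", length(cases)), rep("control", length(ctrls))),
           c(cases, ctrls))
}
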