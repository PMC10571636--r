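#' Project held-out samples onto a discovered profile
#'
#' Appends held-out samples (test individuals, LB-line replicates) to the
#' training samples, restricts to the profile's probes, recomputes the
#' Ward/Euclidean dendrogram, and assigns each held-out sample to the side
#' of the two-cluster cut whose training majority defines its label
#' (case-enriched vs control-enriched). Distances to the training case and
#' control centroids are reported as a continuous diagnostic, since some
#' samples cluster ambiguously, along with two-dimensional MDS coordinates
#' of the combined samples.
#'
#' @param beta_train Beta matrix containing the training samples.
#' @param labels Named `"case"`/`"control"` vector over training samples.
#' @param beta_heldout Beta matrix of held-out samples (same probe space).
#' @param profile A `signature_profile` from [grid_search()], or a character
#'   vector of probe ids.
#' @return A `projection_result`: `assignments` tibble (`sample_id`,
#'   `assignment`, `d_case`, `d_control`, `mds1`, `mds2`), plus `hclust`
#'   over the combined samples and the training `labels`.
#' @export
project <- function(beta_train, labels, beta_heldout, profile) {
  probes <- if (inherits(profile, "signature_profile")) {
    profile$probe_ids
  } else {
    as.character(profile)
  }
  if (length(probes) == 0) abort("Profile has no probes.")
  missing <- setdiff(probes, rownames(beta_heldout))
  if (length(missing) > 0) {
    abort(paste0("Profile probes missing from the held-out matrix: ",
                 paste(utils::head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) sprintf(" (+%d more)",
                                                  length(missing) - 5)))
  }
  train_ids <- names(labels)
  held_ids <- colnames(beta_heldout)
  Xt <- t(beta_train[probes, train_ids, drop = FALSE])
  Xh <- t(beta_heldout[probes, held_ids, drop = FALSE])
  X <- rbind(Xt, Xh)

  d <- dist(X)
  hc <- hclust(d, method = "ward.D2")
  k2 <- cutree(hc, k = 2)

  side_label <- function(side) {
    members <- intersect(names(k2)[k2 == side], train_ids)
    if (length(members) == 0) return(NA_character_)
    tab <- table(labels[members])
    paste0(names(which.max(tab)), "_enriched")
  }
  side_labels <- vapply(1:2, side_label, character(1))

  ctr_case <- colMeans(Xt[labels == "case", , drop = FALSE])
  ctr_ctrl <- colMeans(Xt[labels == "control", , drop = FALSE])
  d_case <- sqrt(rowSums(sweep(Xh, 2, ctr_case)^2))
  d_ctrl <- sqrt(rowSums(sweep(Xh, 2, ctr_ctrl)^2))

  assignment <- side_labels[k2[held_ids]]
  # a cut side holding no training samples carries no vote; fall back to the
  # nearer training centroid
  no_side <- is.na(assignment)
  assignment[no_side] <- ifelse(d_case[no_side] <= d_ctrl[no_side],
                                "case_enriched", "control_enriched")

  mds <- cmdscale(d, k = 2)
  structure(
    list(
      assignments = tibble(
        sample_id = held_ids,
        assignment = unname(assignment),
        d_case = unname(d_case),
        d_control = unname(d_ctrl),
        mds1 = unname(mds[held_ids, 1]),
        mds2 = unname(mds[held_ids, 2])
      ),
      hclust = hc,
      labels = labels
    ),
    class = "projection_result"
  )
}

#' @export
print.projection_result <- function(x, ...) {
  tab <- table(x$assignments$assignment)
  cat(sprintf("<projection_result> %d held-out samples: %s\n",
              nrow(x$assignments),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @rdname project
#' @param x A `projection_result`.
#' @param ... Unused.
#' @export
tidy.projection_result <- function(x, ...) x$assignments
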