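# Readers and writers for the package's on-disk formats. Matrices are TSV
# with probes as rows and the probe id in the first column; sample metadata
# and manifests are CSV with fixed headers; structured results are JSON
# carrying a schema version.

SCHEMA_VERSION <- "1.0"

#' Write / read a probes-by-samples matrix as TSV
#'
#' @param x Numeric matrix with probe rownames and sample colnames.
#' @param path File path.
#' @return `write_matrix_tsv()` returns `path` invisibly;
#'   `read_matrix_tsv()` returns the matrix.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- dplyr::bind_cols(tibble(probe_id = rownames(x)), as_tibble(x))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  m
}

#' Write / read a probe manifest as CSV
#'
#' Fixed header: `probe_id, chromosome, position, cross_reactive,
#' snp_overlap`.
#' @param manifest Manifest tibble.
#' @param path File path.
#' @export
write_manifest_csv <- function(manifest, path) {
  readr::write_csv(manifest[, c("probe_id", "chromosome", "position",
                                "cross_reactive", "snp_overlap")], path)
  invisible(path)
}

#' @rdname write_manifest_csv
#' @export
read_manifest_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    probe_id = "c", chromosome = "c", position = "i",
                    cross_reactive = "l", snp_overlap = "l"
                  ))
}

#' Write / read a sample sheet as CSV
#'
#' Fixed leading header `sample_id, group, sex, age, array_type, tissue,
#' replicate_of` followed by one `cell_*` column per cell type.
#' @param sheet Sample-sheet tibble.
#' @param path File path.
#' @export
write_sample_sheet_csv <- function(sheet, path) {
  lead <- c("sample_id", "group", "sex", "age", "array_type", "tissue",
            "replicate_of")
  readr::write_csv(sheet[, c(lead, cell_prop_cols(sheet))], path)
  invisible(path)
}

#' @rdname write_sample_sheet_csv
#' @export
read_sample_sheet_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a differential methylation table as TSV
#'
#' Fixed column order `probe_id, delta_beta, coef, t_mod, p, p_adj, auc`.
#' @param table The `table` of a [diff_methylation()] fit.
#' @param path File path.
#' @export
write_diffmeth_tsv <- function(table, path) {
  readr::write_tsv(table[, c("probe_id", "delta_beta", "coef", "t_mod",
                             "p", "p_adj", "auc")], path)
  invisible(path)
}

#' @rdname write_diffmeth_tsv
#' @export
read_diffmeth_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Serialize a signature profile to JSON
#'
#' @param profile A `signature_profile`.
#' @param path File path.
#' @export
write_profile_json <- function(profile, path) {
  jsonlite::write_json(
    list(
      schema_version = SCHEMA_VERSION,
      probe_ids = profile$probe_ids,
      params = unclass(profile$params),
      score = unclass(profile$score),
      hypo_fraction = profile$hypo_fraction
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(probe_ids = x$probe_ids,
         params = do.call(selection_params, as.list(x$params)),
         score = structure(as.list(x$score), class = "clustering_score"),
         hypo_fraction = x$hypo_fraction,
         n_skipped = NA_integer_, n_evaluated = NA_integer_),
    class = "signature_profile"
  )
}

#' Export a dendrogram in Newick format
#'
#' @param hc An `hclust` object (e.g. from [evaluate_clustering()]).
#' @param path File path.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every stage parameter of [run_pipeline()].
#'
#' @param sim A [sim_config()] describing the dataset to generate, or `NULL`
#'   when `beta`/`manifest`/`detp`/`samples` are supplied directly to
#'   [run_pipeline()].
#' @param detp_threshold Detection-failure p-value cutoff.
#' @param max_failed_fraction Per-sample failed-probe tolerance.
#' @param eps Beta-to-M offset.
#' @param ratio Matched controls per case (3-8).
#' @param grid Selection-parameter grid.
#' @param output_dir Optional directory; when given, every intermediate
#'   artifact is written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            detp_threshold = 0.01,
                            max_failed_fraction = 0.05,
                            eps = 0.01,
                            ratio = 5,
                            grid = default_grid(),
                            output_dir = NULL) {
  structure(
    list(sim = sim, detp_threshold = detp_threshold,
         max_failed_fraction = max_failed_fraction, eps = eps,
         ratio = ratio, grid = grid, output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Run the full episignature-discovery pipeline
#'
#' Chains every stage: sample filtering, probe filtering, matched-control
#' selection, per-probe moderated differential methylation, grid-searched
#' signature selection, clustering evaluation, and projection of held-out
#' samples (when present). A run manifest records parameters and the probe
#' and sample counts after each stage.
#'
#' @param config A [pipeline_config()].
#' @param data Optional `meth_dataset` (as from [generate_dataset()]); when
#'   `NULL`, one is generated from `config$sim`.
#' @return An `episig_run` list: `data`, `beta_filtered`, `match`, `fit`
#'   (a `diffmeth_fit`), `profile`, `clustering`, `projection` (or `NULL`),
#'   `manifest` (the run manifest list).
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(sim = sim_config(n_probes = 2000, n_signature = 40,
#'                                         n_cases = 6, n_controls = 30,
#'                                         n_heldout = 1, n_replicates = 1,
#'                                         seed = 5),
#'                        ratio = 5)
#' run <- run_pipeline(cfg)
#' glance(run$profile)
#' }
run_pipeline <- function(config = pipeline_config(), data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(data)) {
    if (is.null(config$sim)) {
      abort("Either supply `data` or a `sim` entry in the config.")
    }
    data <- generate_dataset(config$sim)
  }
  counts <- list(probes_input = nrow(data$beta),
                 samples_input = ncol(data$beta))

  beta_s <- filter_samples(data$beta, data$detp,
                           max_failed_fraction = config$max_failed_fraction,
                           detp_threshold = config$detp_threshold)
  counts$samples_retained <- ncol(beta_s)

  beta_f <- filter_probes(beta_s, data$manifest,
                          data$detp[, colnames(beta_s), drop = FALSE],
                          detp_threshold = config$detp_threshold)
  filter_report <- attr(beta_f, "filter_report")
  counts$probes_retained <- nrow(beta_f)

  match <- select_controls(
    data$samples[data$samples$sample_id %in% colnames(beta_f), ],
    ratio = config$ratio
  )
  labels <- match_labels(match)

  fit <- diff_methylation(beta_f, data$samples, labels, eps = config$eps)
  beta_train <- beta_f[, names(labels), drop = FALSE]
  profile <- grid_search(fit$table, beta_train, labels, grid = config$grid)
  counts$probes_selected <- length(profile$probe_ids)

  clustering <- evaluate_clustering(beta_train, profile$probe_ids, labels)

  held_ids <- intersect(
    data$samples$sample_id[data$samples$group == "heldout"],
    colnames(beta_f)
  )
  projection <- if (length(held_ids) > 0) {
    project(beta_train, labels,
            beta_f[, held_ids, drop = FALSE], profile)
  } else {
    NULL
  }

  run_manifest <- list(
    schema_version = SCHEMA_VERSION,
    parameters = list(
      detp_threshold = config$detp_threshold,
      max_failed_fraction = config$max_failed_fraction,
      eps = config$eps, ratio = config$ratio,
      n_grid = length(config$grid),
      seed = if (!is.null(config$sim)) config$sim$seed else NA
    ),
    counts = counts,
    filter_report = filter_report,
    prior = unclass(fit$prior),
    selected_params = unclass(profile$params),
    score = unclass(profile$score)
  )

  run <- structure(
    list(data = data, beta_filtered = beta_f, match = match, fit = fit,
         profile = profile, clustering = clustering,
         projection = projection, manifest = run_manifest),
    class = "episig_run"
  )
  if (!is.null(config$output_dir)) write_run(run, config$output_dir)
  run
}

#' @export
print.episig_run <- function(x, ...) {
  cat("<episig_run>\n")
  cat(sprintf("  probes: %d -> %d retained -> %d selected\n",
              x$manifest$counts$probes_input,
              x$manifest$counts$probes_retained,
              x$manifest$counts$probes_selected))
  cat(sprintf("  clustering score %.3g, 2-cut purity %.3f\n",
              x$profile$score$score, x$clustering$purity))
  invisible(x)
}

# Write every pipeline artifact under `dir`.
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(run$beta_filtered, file.path(dir, "beta_filtered.tsv"))
  write_sample_sheet_csv(run$data$samples, file.path(dir, "samples.csv"))
  write_manifest_csv(run$data$manifest, file.path(dir, "manifest.csv"))
  write_diffmeth_tsv(run$fit$table, file.path(dir, "diffmeth.tsv"))
  jsonlite::write_json(
    c(list(schema_version = SCHEMA_VERSION), unclass(run$fit$prior)),
    file.path(dir, "prior.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(schema_version = SCHEMA_VERSION,
         matches = run$match$matches, ratio = run$match$ratio),
    file.path(dir, "match.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows"
  )
  write_profile_json(run$profile, file.path(dir, "profile.json"))
  write_dendrogram_newick(run$clustering$hclust,
                          file.path(dir, "dendrogram.nwk"))
  readr::write_tsv(run$clustering$mds, file.path(dir, "mds.tsv"))
  if (!is.null(run$projection)) {
    readr::write_tsv(run$projection$assignments,
                     file.path(dir, "projection.tsv"))
  }
  jsonlite::write_json(run$manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
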