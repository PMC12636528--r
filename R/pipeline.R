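#' Write / read a study metric table
#'
#' Metric tables are tab-separated, one row per ROI, with the factor
#' columns (`roi_id`, `lizard_id`, `location`, `clade`, `habitat`, `sex`,
#' `svl`, `role`, `is_perch`, `missing`) followed by the 17 metric columns
#' of [metric_names()]. Header comment lines (prefixed `#`) record units
#' and provenance. Reading validates the required columns and factor
#' values and preserves unknown extra columns.
#'
#' @param dataset A `study_dataset` or its `table`.
#' @param path TSV path.
#' @param comments Extra header comment lines.
#' @return `path` (write); a validated data.frame (read).
#' @export
write_metric_table <- function(dataset, path, comments = character(0)) {
  tab <- if (inherits(dataset, "study_dataset")) dataset$table else dataset
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("# camomatch metric table (TSV)",
           "# areas mm^2; edge metrics JND; svl mm; one row per ROI")
  if (length(comments) > 0) hdr <- c(hdr, paste0("# ", comments))
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  req <- c("roi_id", "lizard_id", "location", "clade", "habitat", "sex",
           "svl", "role", "is_perch", "missing", metric_names())
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("metric table is missing required column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!tab$role %in% c("lizard", "background") |
                 is.na(tab$lizard_id) | is.na(tab$location) |
                 is.na(tab$clade) | is.na(tab$sex))
  if (length(bad) > 0)
    stop("malformed metric rows (bad role or missing factors) at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  tab$is_perch <- as.logical(tab$is_perch)
  tab$missing <- as.logical(tab$missing)
  tab
}

#' Pipeline run configuration
#'
#' Collects every tunable of the full pipeline in one serializable object:
#' input mode, viewer parameters, segmentation thresholds, standardization
#' mode, significance levels, adjustment methods and seeds.
#'
#' @param input `"synthetic"` (generate with [generate_study()]) or
#'   `"metric-table"` (read `table_path`).
#' @param table_path Metric-table TSV for `input = "metric-table"`.
#' @param design,effects Generator settings for synthetic input.
#' @param viewer A [viewer_model()].
#' @param standardize `"zscore"` or `"raw"`.
#' @param theta_color,theta_lum Segmentation thresholds (JND), recorded for
#'   provenance when images are processed externally.
#' @param alpha Interaction-screen significance level.
#' @param emm_adjust,hotelling_adjust Multiplicity adjustments.
#' @param n_perm PCA permutation count.
#' @param seed Master seed; every stochastic stage derives from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = c("synthetic", "metric-table"),
                       table_path = NULL,
                       design = study_design(), effects = effect_spec(),
                       viewer = viewer_model(),
                       standardize = "zscore",
                       theta_color = 3, theta_lum = 3,
                       alpha = 0.05, emm_adjust = "holm",
                       hotelling_adjust = "bonferroni",
                       n_perm = 999L, seed = 1L) {
  input <- match.arg(input)
  if (input == "metric-table" && is.null(table_path))
    stop("metric-table input requires table_path")
  structure(list(input = input, table_path = table_path, design = design,
                 effects = effects, viewer = viewer,
                 standardize = standardize, theta_color = theta_color,
                 theta_lum = theta_lum, alpha = alpha,
                 emm_adjust = emm_adjust,
                 hotelling_adjust = hotelling_adjust,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields of [run_config()] may be set in a YAML file; design and
#' effect fields are passed through to [study_design()] / [effect_spec()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- do.call(study_design, y$design %||% list())
  effects <- do.call(effect_spec, y$effects %||% list())
  viewer <- do.call(viewer_model, y$viewer %||% list())
  args <- y[setdiff(names(y), c("design", "effects", "viewer"))]
  do.call(run_config, c(args, list(design = design, effects = effects,
                                   viewer = viewer)))
}

#' Run the full background-matching pipeline
#'
#' Executes every stage on one dataset: synthetic generation (or metric-
#' table input), component-space assembly with the visual-space PCA,
#' per-microhabitat matching (optimal-background calls, clade proportion
#' tests, interaction GLMs of perch distance and perch-to-optimal
#' distance), convex-hull diversity with its GLMs, and the range-wide
#' distance-matrix stage with Hotelling comparisons. When `outdir` is
#' given, all tables are written as TSV along with a JSON run manifest
#' (configuration, seeds, decisions taken) sufficient to reproduce the run.
#'
#' @param config A [run_config()].
#' @param outdir Optional output directory.
#' @return A result bundle (list): `dataset`, `spaces`, `matching`
#'   (`distances`, `optimal`, `proportion_tests`, `glm_perch`,
#'   `glm_perch_optimal`), `diversity` (`hulls`, `glm`), `rangewide`, and
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  dataset <- if (config$input == "synthetic") {
    generate_study(config$design, config$effects, seed = config$seed)
  } else {
    tab <- read_metric_table(config$table_path)
    structure(list(table = tab, design = NULL, effects = NULL,
                   seed = config$seed), class = "study_dataset")
  }
  spaces <- build_component_spaces(dataset,
                                   standardize = config$standardize,
                                   n_perm = config$n_perm,
                                   seed = config$seed + 1L)
  match <- matching_analysis(spaces)

  prop_tests <- list()
  for (sp in unique(match$optimal$space)) {
    sub <- match$optimal[match$optimal$space == sp, ]
    agg_n <- table(sub$clade)
    agg_x <- tapply(sub$on_optimal, sub$clade, sum)
    prop_tests[[sp]] <- proportion_test_by_clade(
      stats::setNames(as.vector(agg_x), names(agg_x)),
      stats::setNames(as.vector(agg_n), names(agg_n)))
  }

  glm_perch <- list(); glm_po <- list()
  transforms <- c(cluster = "identity", edge = "log10", visual = "log10")
  transforms_po <- c(cluster = "sqrt", edge = "log10", visual = "log10")
  for (sp in names(spaces$spaces)) {
    sub <- match$optimal[match$optimal$space == sp, ]
    sub$d_perch <- sub$d_lizard_perch
    glm_perch[[sp]] <- tryCatch(
      fit_matching_glm(sub, "d_perch", transform = transforms[[sp]],
                       alpha = config$alpha),
      error = function(e) e)
    off <- sub[!sub$on_optimal & !is.na(sub$d_perch_to_optimal), ]
    glm_po[[sp]] <- tryCatch(
      fit_matching_glm(off, "d_perch_to_optimal",
                       transform = transforms_po[[sp]],
                       alpha = config$alpha),
      error = function(e) e)
  }

  hulls <- microhabitat_hulls(spaces)
  div_glm <- list()
  for (sp in names(spaces$spaces)) {
    div_glm[[sp]] <- tryCatch(
      fit_diversity_glm(hulls[hulls$space == sp, ], alpha = config$alpha),
      error = function(e) e)
  }

  rw <- rangewide_analysis(spaces, adjust = config$hotelling_adjust)

  manifest <- list(
    package_version = as.character(utils::packageVersion("camomatch")),
    seed = config$seed, input = config$input,
    standardize = config$standardize,
    n_perm = config$n_perm, alpha = config$alpha,
    emm_adjust = config$emm_adjust,
    hotelling_adjust = config$hotelling_adjust,
    glm_ss_types = lapply(glm_perch, function(g)
      if (inherits(g, "matching_glm")) g$ss_type else NA),
    n_lizards = sum(spaces$meta$role == "lizard"),
    n_backgrounds = sum(spaces$meta$role == "background"))

  bundle <- list(dataset = dataset, spaces = spaces,
                 matching = c(match, list(proportion_tests = prop_tests,
                                          glm_perch = glm_perch,
                                          glm_perch_optimal = glm_po)),
                 diversity = list(hulls = hulls, glm = div_glm),
                 rangewide = rw, manifest = manifest)
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name)
    utils::write.table(x, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_metric_table(bundle$dataset, file.path(outdir, "metric_table.tsv"))
  tsv(bundle$matching$distances, "microhabitat_distances.tsv")
  tsv(bundle$matching$optimal, "optimal_calls.tsv")
  tsv(bundle$diversity$hulls, "hulls.tsv")
  for (sp in names(bundle$rangewide$matrices))
    tsv(as.data.frame(bundle$rangewide$matrices[[sp]]),
        sprintf("distance_matrix_%s.tsv", sp))
  for (g in names(bundle$rangewide$hotelling))
    tsv(bundle$rangewide$hotelling[[g]]$results,
        sprintf("hotelling_%s.tsv", g))
  for (sp in names(bundle$matching$glm_perch)) {
    g <- bundle$matching$glm_perch[[sp]]
    if (inherits(g, "matching_glm"))
      tsv(g$term_table, sprintf("glm_perch_%s.tsv", sp))
  }
  write_pca_fit(bundle$spaces$pca, file.path(outdir, "pca_fit.json"))
  jsonlite::write_json(bundle$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
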