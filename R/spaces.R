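#' Fit the visual-model component space
#'
#' Principal components analysis of the twelve secondary colour-pattern
#' statistics, on centred and unit-scaled variables, with a permutation test
#' of component support: each variable is independently permuted `n_perm`
#' times, and an observed eigenvalue is flagged supported when it exceeds
#' the 95th percentile of its null eigenvalues. The first three components
#' are always retained for the downstream pipeline; the support flags are
#' reported alongside. The null draws resample each column's sorted values,
#' so the null stream does not depend on the row order of the input.
#'
#' @param stats_matrix n x 12 numeric matrix (n >= 13) of secondary
#'   statistics, one row per ROI.
#' @param n_perm Number of permutations (a warning is issued below 99).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `pca_fit`: `centers`, `scales`, `rotation`,
#'   `eigenvalues`, `scores`, `null_q95`, `supported`, `n_retained` (3),
#'   `dropped` (constant columns removed), `n_perm`, `seed`.
#' @export
fit_visual_space <- function(stats_matrix, n_perm = 999L, seed = 1L) {
  X <- as.matrix(stats_matrix)
  if (nrow(X) < ncol(X) + 1L)
    stop("need at least p + 1 rows to fit the visual space")
  if (anyNA(X)) stop("missing values in the statistics matrix")
  const <- apply(X, 2L, function(v) stats::sd(v) == 0)
  dropped <- colnames(X)[const]
  if (any(const)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (n_perm < 99L) warning("n_perm < 99 gives a coarse permutation null")
  p <- ncol(X)
  fit <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  eig <- fit$sdev^2
  sorted_cols <- apply(X, 2L, sort)
  set.seed(as.integer(seed))
  null_eig <- matrix(0, n_perm, p)
  for (b in seq_len(n_perm)) {
    Xp <- apply(sorted_cols, 2L, sample)
    null_eig[b, ] <- stats::prcomp(Xp, center = TRUE, scale. = TRUE)$sdev^2
  }
  q95 <- apply(null_eig, 2L, stats::quantile, probs = 0.95)
  structure(list(centers = fit$center, scales = fit$scale,
                 rotation = fit$rotation, eigenvalues = eig,
                 scores = fit$x, null_q95 = q95,
                 supported = eig > q95, n_retained = 3L,
                 dropped = dropped, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "pca_fit")
}

#' @export
print.pca_fit <- function(x, ...) {
  cat("visual-space PCA fit on", length(x$centers), "variables\n")
  cat("  eigenvalues:", paste(signif(x$eigenvalues[1:3], 3), collapse = ", "),
      "... (first three retained)\n")
  cat("  supported components:", sum(x$supported), "of", length(x$supported),
      sprintf("(%d permutations)\n", x$n_perm))
  invisible(x)
}

#' Project secondary statistics into the visual space
#'
#' Centres and scales a 12-statistic row (or matrix of rows) with the fit's
#' parameters and returns the scores on the first three components.
#'
#' @param stats_row Numeric vector (length 12) or n x 12 matrix.
#' @param fit A [fit_visual_space()] result.
#' @return A 3-vector (or n x 3 matrix) of PC1-3 scores.
#' @export
project_visual <- function(stats_row, fit) {
  stopifnot(inherits(fit, "pca_fit"))
  X <- rbind(stats_row)
  if (is.matrix(stats_row)) X <- stats_row
  if (!is.null(colnames(X)) && all(names(fit$centers) %in% colnames(X)))
    X <- X[, names(fit$centers), drop = FALSE]
  if (ncol(X) != length(fit$centers))
    stop("row length does not match the fitted variables")
  if (anyNA(X)) stop("missing values cannot be projected")
  Z <- sweep(sweep(X, 2L, fit$centers, "-"), 2L, fit$scales, "/")
  out <- Z %*% fit$rotation[, seq_len(fit$n_retained), drop = FALSE]
  if (!is.matrix(stats_row)) out <- out[1L, ]
  out
}

#' Standardize a component space
#'
#' Z-scores each coordinate over all rows jointly (lizards and backgrounds
#' alike), so that Euclidean distances weight incommensurate variables
#' (counts, areas, JNDs) equally; `raw` returns the input unchanged for
#' sensitivity analyses.
#'
#' @param vectors Numeric matrix, one ROI per row.
#' @param mode `"zscore"` or `"raw"`.
#' @return The (possibly) standardized matrix, with `centers` and `scales`
#'   attributes in zscore mode.
#' @export
standardize_space <- function(vectors, mode = c("zscore", "raw")) {
  mode <- match.arg(mode)
  X <- as.matrix(vectors)
  if (mode == "raw") return(X)
  if (nrow(X) < 2L) stop("zscore standardization needs at least 2 rows")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  if (any(scl == 0)) {
    warning("zero-variance coordinate(s) left centred with scale 1")
    scl[scl == 0] <- 1
  }
  out <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  attr(out, "centers") <- ctr
  attr(out, "scales") <- scl
  out
}

#' Assemble the three component spaces of a study dataset
#'
#' Builds, from the metric table of a [generate_study()] dataset (or a table
#' read by [read_metric_table()]), the three per-ROI component spaces used
#' throughout the analysis: cluster (number of clusters, counts within
#' clusters, area of largest cluster; 3D), edge intensity (mean colour and
#' luminance local edge contrast; 2D) and visual model (PC1-3 of the twelve
#' secondary statistics; 3D). The PCA is fitted on all usable ROI rows
#' jointly so lizards and backgrounds share one space, and each space is
#' standardized according to `standardize`.
#'
#' @param dataset A `study_dataset` (or its `table` data.frame).
#' @param standardize `"zscore"` (default) or `"raw"`.
#' @param n_perm,seed Passed to [fit_visual_space()].
#' @return An object of class `component_spaces`: `meta` (factor columns of
#'   the usable rows), `spaces` (named list of matrices `cluster` n x 3,
#'   `edge` n x 2, `visual` n x 3), `pca` (the [fit_visual_space()] fit) and
#'   `standardize`.
#' @export
build_component_spaces <- function(dataset, standardize = c("zscore", "raw"),
                                   n_perm = 999L, seed = 1L) {
  standardize <- match.arg(standardize)
  tab <- if (inherits(dataset, "study_dataset")) dataset$table else dataset
  tab <- tab[!tab$missing, , drop = FALSE]
  meta_cols <- c("roi_id", "lizard_id", "location", "clade", "habitat",
                 "sex", "svl", "role", "is_perch")
  meta <- tab[, meta_cols]
  cluster <- as.matrix(tab[, c("n_clusters", "counts_within",
                               "area_largest")])
  edge <- as.matrix(tab[, c("edge_color", "edge_lum")])
  sec <- as.matrix(tab[, secondary_stat_names()])
  pca <- fit_visual_space(sec, n_perm = n_perm, seed = seed)
  visual <- project_visual(sec, pca)
  colnames(visual) <- c("PC1", "PC2", "PC3")
  spaces <- list(cluster = standardize_space(cluster, standardize),
                 edge = standardize_space(edge, standardize),
                 visual = standardize_space(visual, standardize))
  rownames(spaces$cluster) <- rownames(spaces$edge) <-
    rownames(spaces$visual) <- tab$roi_id
  structure(list(meta = meta, spaces = spaces, pca = pca,
                 standardize = standardize),
            class = "component_spaces")
}

#' @export
print.component_spaces <- function(x, ...) {
  cat(sprintf(paste0("component_spaces: %d ROIs (%d lizards), ",
                     "standardization %s\n"),
              nrow(x$meta), sum(x$meta$role == "lizard"), x$standardize))
  invisible(x)
}

#' Serialize / restore a PCA fit
#'
#' Stores centres, scales, loadings, eigenvalues and the permutation summary
#' as JSON so projections are reproducible across sessions.
#'
#' @param fit A `pca_fit`.
#' @param path Output JSON path.
#' @return `path` (write) or a restored `pca_fit` (read).
#' @export
write_pca_fit <- function(fit, path) {
  stopifnot(inherits(fit, "pca_fit"))
  obj <- list(centers = as.list(fit$centers), scales = as.list(fit$scales),
              rotation = as.data.frame(fit$rotation),
              eigenvalues = fit$eigenvalues, null_q95 = fit$null_q95,
              supported = fit$supported, n_retained = fit$n_retained,
              dropped = fit$dropped, n_perm = fit$n_perm, seed = fit$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pca_fit
#' @export
read_pca_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rot <- as.matrix(obj$rotation)
  structure(list(centers = unlist(obj$centers), scales = unlist(obj$scales),
                 rotation = rot, eigenvalues = obj$eigenvalues,
                 scores = NULL, null_q95 = obj$null_q95,
                 supported = obj$supported,
                 n_retained = obj$n_retained,
                 dropped = obj$dropped %||% character(0),
                 n_perm = obj$n_perm, seed = obj$seed),
            class = "pca_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
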