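#' All lizard-by-background distances in one space
#'
#' Full Euclidean distance matrix between every lizard and every usable
#' background across all microhabitats and locations (a lizard's own
#' backgrounds included). With the default study design this is a 52 x 309
#' matrix, i.e. 16,068 distances per component space.
#'
#' @param lizards n x d matrix of lizard coordinates (rownames = ids).
#' @param backgrounds m x d matrix of background coordinates.
#' @return n x m matrix of distances.
#' @export
all_pairs_distances <- function(lizards, backgrounds) {
  L <- as.matrix(lizards); B <- as.matrix(backgrounds)
  if (nrow(B) == 0L) stop("empty background set")
  if (ncol(L) != ncol(B)) stop("dimension mismatch")
  ll <- rowSums(L^2); bb <- rowSums(B^2)
  d2 <- outer(ll, bb, "+") - 2 * L %*% t(B)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  dimnames(d) <- list(rownames(L), rownames(B))
  d
}

#' Per-lizard, per-location mean distances
#'
#' Averages each lizard's distances over the backgrounds of every location,
#' with the standard error over that location's backgrounds; one point per
#' lizard x location (364 with the default 52-lizard, 7-location design).
#'
#' @param dmat Distance matrix from [all_pairs_distances()].
#' @param background_locations Location of each background (column).
#' @return A data.frame: `lizard_id`, `location`, `mean`, `se`, `n`.
#' @export
location_means <- function(dmat, background_locations) {
  stopifnot(length(background_locations) == ncol(dmat))
  locs <- unique(background_locations)
  empty <- setdiff(locs, background_locations)
  out <- list()
  lids <- rownames(dmat)
  if (is.null(lids)) lids <- sprintf("L%03d", seq_len(nrow(dmat)))
  for (loc in locs) {
    cols <- which(background_locations == loc)
    if (length(cols) == 0L) {
      warning("location with no backgrounds dropped: ", loc)
      next
    }
    sub <- dmat[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    se <- if (length(cols) >= 2L) {
      apply(sub, 1L, stats::sd) / sqrt(length(cols))
    } else rep(NA_real_, nrow(sub))
    out[[loc]] <- data.frame(lizard_id = lids, location = loc,
                             mean = unname(mu), se = unname(se),
                             n = length(cols), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hotelling's T-squared two-sample test
#'
#' Compares two multivariate samples with the pooled-covariance Hotelling
#' statistic \eqn{T^2 = \frac{n_1 n_2}{n_1 + n_2}
#' (\bar x_1 - \bar x_2)^\top S_p^{-1} (\bar x_1 - \bar x_2)}. The
#' large-sample chi-square form (statistic `T2`, df = p) is reported as
#' primary; the exact-F version is included alongside.
#'
#' @param points_a,points_b n1 x p and n2 x p matrices.
#' @return A list of class `hotelling_result`: `T2`, `chisq`, `df`,
#'   `p.value` (chi-square), `F`, `df1`, `df2`, `p.value.F`, `n1`, `n2`,
#'   `p`.
#' @examples
#' hotelling_t2(cbind(c(1, 2, 3)), cbind(c(4, 5, 6)))$T2  # 13.5
#' @export
hotelling_t2 <- function(points_a, points_b) {
  A <- as.matrix(points_a); B <- as.matrix(points_b)
  p <- ncol(A)
  stopifnot(ncol(B) == p)
  n1 <- nrow(A); n2 <- nrow(B)
  if (n1 + n2 <= p + 1L)
    stop("too few observations for the dimension (need n1 + n2 > p + 1)")
  dbar <- colMeans(A) - colMeans(B)
  Sp <- ((n1 - 1) * stats::cov(A) + (n2 - 1) * stats::cov(B)) / (n1 + n2 - 2)
  sol <- tryCatch(solve(Sp, dbar), error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol)))
    stop(paste("singular pooled covariance; reduce the dimension or use",
               "fewer collinear variables"))
  T2 <- (n1 * n2 / (n1 + n2)) * sum(dbar * sol)
  Fstat <- (n1 + n2 - p - 1) / (p * (n1 + n2 - 2)) * T2
  structure(list(T2 = unname(T2), chisq = unname(T2), df = p,
                 p.value = stats::pchisq(T2, p, lower.tail = FALSE),
                 F = unname(Fstat), df1 = p, df2 = n1 + n2 - p - 1,
                 p.value.F = stats::pf(Fstat, p, n1 + n2 - p - 1,
                                       lower.tail = FALSE),
                 n1 = n1, n2 = n2, p = p),
            class = "hotelling_result")
}

#' @export
print.hotelling_result <- function(x, ...) {
  cat(sprintf("Hotelling T2 = %.4g, chi-square df = %d, p = %.4g (n = %d, %d)\n",
              x$T2, x$df, x$p.value, x$n1, x$n2))
  invisible(x)
}

#' Pairwise Hotelling comparisons between groups
#'
#' Tests every unordered pair of groups in a multivariate point set, with a
#' multiplicity adjustment (Bonferroni by default), and exports the
#' chi-square statistics as a symmetric heat-map matrix. Pairs where a
#' group is smaller than p + 2 are flagged untestable.
#'
#' @param points n x p matrix.
#' @param groups Group label per row.
#' @param adjust Method for [stats::p.adjust()].
#' @return A list: `results` (one row per pair: groups, n, chisq, df, raw
#'   and adjusted p, `testable`) and `chisq_matrix`.
#' @export
pairwise_hotelling <- function(points, groups, adjust = "bonferroni") {
  X <- as.matrix(points)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(X))
  gl <- unique(groups)
  if (length(gl) < 2L) stop("need at least two groups")
  p <- ncol(X)
  pairs <- utils::combn(gl, 2L)
  rows <- list()
  M <- matrix(0, length(gl), length(gl), dimnames = list(gl, gl))
  for (i in seq_len(ncol(pairs))) {
    g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
    A <- X[groups == g1, , drop = FALSE]
    B <- X[groups == g2, , drop = FALSE]
    testable <- nrow(A) >= p + 2L && nrow(B) >= p + 2L
    if (testable) {
      ht <- tryCatch(hotelling_t2(A, B), error = function(e) NULL)
      if (is.null(ht)) testable <- FALSE
    }
    if (testable) {
      rows[[i]] <- data.frame(group1 = g1, group2 = g2,
                              n1 = nrow(A), n2 = nrow(B),
                              chisq = ht$chisq, df = ht$df,
                              p_raw = ht$p.value, testable = TRUE,
                              stringsAsFactors = FALSE)
      M[g1, g2] <- M[g2, g1] <- ht$chisq
    } else {
      rows[[i]] <- data.frame(group1 = g1, group2 = g2,
                              n1 = nrow(A), n2 = nrow(B),
                              chisq = NA_real_, df = p,
                              p_raw = NA_real_, testable = FALSE,
                              stringsAsFactors = FALSE)
      M[g1, g2] <- M[g2, g1] <- NA_real_
    }
  }
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p_raw, method = adjust)
  list(results = res, chisq_matrix = M)
}

#' Within- versus between-location distance summary
#'
#' For each location and space: the mean lizard-background distance of that
#' location's lizards to backgrounds inside the location versus to all
#' backgrounds outside it, flagging locations where the outside mean is
#' lower than the within mean (matching there is relatively poor).
#'
#' @param dmat Distance matrix from [all_pairs_distances()].
#' @param lizard_locations Location per lizard (row).
#' @param background_locations Location per background (column).
#' @return A data.frame: `location`, `n_lizards`, `within_mean`,
#'   `outside_mean`, `outside_lower`.
#' @export
within_vs_between <- function(dmat, lizard_locations, background_locations) {
  stopifnot(length(lizard_locations) == nrow(dmat),
            length(background_locations) == ncol(dmat))
  locs <- unique(c(lizard_locations, background_locations))
  out <- list()
  for (loc in locs) {
    lr <- which(lizard_locations == loc)
    if (length(lr) == 0L) next
    bc_in <- which(background_locations == loc)
    bc_out <- which(background_locations != loc)
    wm <- if (length(bc_in) > 0L)
      mean(dmat[lr, bc_in, drop = FALSE]) else NA_real_
    om <- if (length(bc_out) > 0L)
      mean(dmat[lr, bc_out, drop = FALSE]) else NA_real_
    out[[loc]] <- data.frame(
      location = loc, n_lizards = length(lr),
      within_mean = wm, outside_mean = om,
      outside_lower = !is.na(wm) && !is.na(om) && om < wm,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Range-wide analysis of a study dataset
#'
#' Runs the species-wide stage for every component space: the full
#' lizard x background distance matrix, per-location means, pairwise
#' Hotelling comparisons of the 3D location-mean points grouped by clade,
#' habitat and location, and the within- versus between-location summary.
#'
#' @param spaces A [build_component_spaces()] result.
#' @param adjust Multiplicity adjustment for the pairwise tests.
#' @return A list with `matrices` (per space), `location_means` (per-space
#'   long table and a wide 3D point table `points3d`), `hotelling` (per
#'   grouping factor), and `within_between` (per space).
#' @export
rangewide_analysis <- function(spaces, adjust = "bonferroni") {
  stopifnot(inherits(spaces, "component_spaces"))
  meta <- spaces$meta
  liz <- meta$role == "lizard"
  bg <- meta$role == "background"
  mats <- list(); lmeans <- list(); wb <- list()
  for (sp in names(spaces$spaces)) {
    M <- spaces$spaces[[sp]]
    L <- M[liz, , drop = FALSE]; B <- M[bg, , drop = FALSE]
    rownames(L) <- meta$lizard_id[liz]; rownames(B) <- meta$roi_id[bg]
    dmat <- all_pairs_distances(L, B)
    mats[[sp]] <- dmat
    lmeans[[sp]] <- location_means(dmat, meta$location[bg])
    wb[[sp]] <- within_vs_between(dmat, meta$location[liz],
                                  meta$location[bg])
  }
  # one 3D point per lizard x location: (cluster, edge, visual) means
  pts <- lmeans[[1L]][, c("lizard_id", "location")]
  for (sp in names(lmeans)) pts[[sp]] <- lmeans[[sp]]$mean
  fac <- unique(meta[liz, c("lizard_id", "clade", "habitat")])
  pts <- merge(pts, fac, by = "lizard_id", sort = FALSE)
  X <- as.matrix(pts[, names(spaces$spaces)])
  hot <- list(
    clade = pairwise_hotelling(X, pts$clade, adjust = adjust),
    habitat = pairwise_hotelling(X, pts$habitat, adjust = adjust),
    location = pairwise_hotelling(X, pts$location, adjust = adjust))
  list(matrices = mats, location_means = lmeans, points3d = pts,
       hotelling = hot, within_between = wb)
}
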