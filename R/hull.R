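#' Convex-hull measure of a point set
#'
#' Exact area (2D) or volume (3D) of the convex hull of a point set, used
#' as the diversity of a microhabitat's background options. Fewer than
#' d + 1 points, or an affinely dependent set (all points on a line/plane),
#' is degenerate with measure 0.
#'
#' The 2D hull uses [grDevices::chull()] with the shoelace formula. The 3D
#' volume enumerates hull facets by brute force on deterministically
#' jittered points (relative scale 1e-9, to put ties in general position)
#' and sums the tetrahedra they span with the point centroid; the jitter
#' bounds the relative error at ~1e-8.
#'
#' @param points m x d numeric matrix, d = 2 or 3.
#' @return A list: `measure` and `degenerate`.
#' @examples
#' hull_measure(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
#' @export
hull_measure <- function(points) {
  P <- as.matrix(points)
  if (!all(is.finite(P))) stop("non-finite coordinates")
  d <- ncol(P)
  if (!d %in% c(2L, 3L)) stop("hull measure is defined for 2 or 3 dimensions")
  m <- nrow(P)
  if (m < d + 1L || affine_rank(P) < d)
    return(list(measure = 0, degenerate = TRUE))
  measure <- if (d == 2L) hull_area_2d(P) else hull_volume_3d(P)
  list(measure = measure, degenerate = FALSE)
}

affine_rank <- function(P) {
  C <- sweep(P, 2L, colMeans(P), "-")
  s <- svd(C)$d
  sum(s > max(s) * 1e-10 * max(dim(P)))
}

hull_area_2d <- function(P) {
  h <- grDevices::chull(P[, 1L], P[, 2L])
  x <- P[h, 1L]; y <- P[h, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

hull_volume_3d <- function(P) {
  m <- nrow(P)
  scale <- max(apply(P, 2L, function(v) diff(range(v))), 1e-12)
  # deterministic jitter for general position (hash of coordinates)
  jit <- matrix(sin(seq_len(3L * m) * 12.9898 + 78.233) * 43758.5453, m, 3L)
  jit <- (jit - floor(jit) - 0.5) * 2e-9 * scale
  Q <- P + jit
  ctr <- colMeans(Q)
  vol <- 0
  tol <- 1e-12 * scale^3
  for (i in seq_len(m - 2L)) {
    for (j in (i + 1L):(m - 1L)) {
      for (k in (j + 1L):m) {
        n <- cross3(Q[j, ] - Q[i, ], Q[k, ] - Q[i, ])
        s <- (Q %*% n) - sum(n * Q[i, ])
        s <- s[-c(i, j, k)]
        if (all(s <= tol) || all(s >= -tol)) {
          # hull facet: tetrahedron with the interior centroid
          v <- abs(det(rbind(Q[i, ] - ctr, Q[j, ] - ctr, Q[k, ] - ctr))) / 6
          vol <- vol + v
        }
      }
    }
  }
  vol
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Background-diversity hulls of every microhabitat
#'
#' For each lizard and component space, the convex-hull measure (3D volume
#' for cluster and visual, 2D area for edge) of its usable background
#' options, perch included, in the standardized coordinates used for the
#' distance analyses.
#'
#' @param spaces A [build_component_spaces()] result.
#' @return A data.frame: `lizard_id`, `space`, `n_points`, `measure`,
#'   `degenerate`, plus the lizard's factors.
#' @export
microhabitat_hulls <- function(spaces) {
  stopifnot(inherits(spaces, "component_spaces"))
  meta <- spaces$meta
  lids <- unique(meta$lizard_id[meta$role == "lizard"])
  out <- list()
  for (sp in names(spaces$spaces)) {
    M <- spaces$spaces[[sp]]
    for (lid in lids) {
      brow <- which(meta$role == "background" & meta$lizard_id == lid)
      h <- hull_measure(M[brow, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        lizard_id = lid, space = sp, n_points = length(brow),
        measure = h$measure, degenerate = h$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  fac <- unique(meta[meta$role == "lizard",
                     c("lizard_id", "location", "clade", "habitat",
                       "sex", "svl")])
  merge(tab, fac, by = "lizard_id", sort = FALSE)
}

#' GLM of background diversity
#'
#' Models the log10 hull measure as a function of sex, habitat, clade and
#' SVL with the same interaction screen and Type I/II/III machinery as
#' [fit_matching_glm()]. Degenerate (zero-measure) hulls are excluded,
#' their count reported in the result.
#'
#' @param hull_table Output of [microhabitat_hulls()], restricted to one
#'   space.
#' @param transform Response transform (default `"log10"`).
#' @param alpha Interaction screen level.
#' @return A `matching_glm` object with an extra `n_degenerate` element.
#' @export
fit_diversity_glm <- function(hull_table, transform = "log10",
                              alpha = 0.05) {
  n_deg <- sum(hull_table$degenerate)
  tab <- hull_table[!hull_table$degenerate, , drop = FALSE]
  if (nrow(tab) == 0L) stop("all hulls are degenerate")
  fit <- fit_matching_glm(tab, response = "measure",
                          transform = transform, alpha = alpha)
  fit$n_degenerate <- n_deg
  fit
}
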