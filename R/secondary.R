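#' Names of the twelve secondary colour-pattern statistics
#'
#' Four colour-adjacency (CAA), four visual-contrast (VCA) and four
#' boundary-strength (BSA) statistics, in the fixed order used throughout
#' the package.
#'
#' @return Character vector of length 12.
#' @export
secondary_stat_names <- function() {
  c("caa_div", "caa_even", "caa_trans_div", "caa_hv_ratio",
    "vca_col_mean", "vca_col_cv", "vca_lum_mean", "vca_lum_cv",
    "bsa_col_mean", "bsa_col_cv", "bsa_lum_mean", "bsa_lum_cv")
}

#' Secondary colour-pattern statistics
#'
#' Twelve summary statistics of a segmented pattern, covering colour
#' diversity and complexity (colour adjacency analysis, CAA), pattern
#' contrast (visual contrast analysis, VCA) and contrast at cluster
#' boundaries (boundary strength analysis, BSA):
#'
#' * `caa_div` — Shannon diversity of cluster area proportions;
#' * `caa_even` — evenness, `caa_div / ln(n_clusters)` (1 for one cluster);
#' * `caa_trans_div` — Shannon diversity of off-diagonal (between-cluster)
#'   adjacency transitions;
#' * `caa_hv_ratio` — horizontal:vertical between-cluster transition ratio,
#'   Laplace-smoothed as `(h + 1)/(v + 1)` so it is finite and 1 for a
#'   uniform image;
#' * `vca_col_mean`, `vca_lum_mean` — area-weighted (weights
#'   \eqn{p_i p_j}) mean pairwise chromatic / luminance RNL contrast
#'   between cluster means, in JND;
#' * `vca_col_cv`, `vca_lum_cv` — weighted coefficients of variation of the
#'   same contrasts;
#' * `bsa_col_mean`, `bsa_lum_mean` — boundary-length-weighted mean
#'   chromatic / luminance contrast across adjacent cluster pairs;
#' * `bsa_col_cv`, `bsa_lum_cv` — their weighted CVs.
#'
#' A single-cluster ROI yields zero diversities, contrasts and CVs, evenness
#' 1 and transition ratio 1.
#'
#' @param seg A [segment_rnl()] result.
#' @param viewer A [viewer_model()].
#' @return Named numeric vector of length 12 (see [secondary_stat_names()]).
#' @export
secondary_stats <- function(seg, viewer = viewer_model()) {
  stopifnot(inherits(seg, "segmented_pattern"))
  k <- nrow(seg$means)
  out <- stats::setNames(numeric(12L), secondary_stat_names())
  out["caa_even"] <- 1
  out["caa_hv_ratio"] <- 1
  p <- seg$areas_px / sum(seg$areas_px)
  out["caa_div"] <- shannon(p)
  if (k > 1L) {
    out["caa_even"] <- out["caa_div"] / log(k)
    # between-cluster transitions (unordered, off-diagonal)
    tr <- seg$adjacency[upper.tri(seg$adjacency)]
    if (sum(tr) > 0) out["caa_trans_div"] <- shannon(tr / sum(tr))
    h <- sum(seg$adjacency_h[upper.tri(seg$adjacency_h)])
    v <- sum(seg$adjacency_v[upper.tri(seg$adjacency_v)])
    out["caa_hv_ratio"] <- (h + 1) / (v + 1)

    ij <- which(upper.tri(diag(k)), arr.ind = TRUE)
    dcol <- rnl_chromatic_distance(seg$means[ij[, 1L], 1:4, drop = FALSE],
                                   seg$means[ij[, 2L], 1:4, drop = FALSE],
                                   viewer)
    dlum <- rnl_luminance_distance(seg$means[ij[, 1L], 5L],
                                   seg$means[ij[, 2L], 5L], viewer)
    w_area <- p[ij[, 1L]] * p[ij[, 2L]]
    out["vca_col_mean"] <- wmean(dcol, w_area)
    out["vca_col_cv"] <- wcv(dcol, w_area)
    out["vca_lum_mean"] <- wmean(dlum, w_area)
    out["vca_lum_cv"] <- wcv(dlum, w_area)

    w_bnd <- seg$adjacency[cbind(ij[, 1L], ij[, 2L])]
    if (sum(w_bnd) > 0) {
      out["bsa_col_mean"] <- wmean(dcol, w_bnd)
      out["bsa_col_cv"] <- wcv(dcol, w_bnd)
      out["bsa_lum_mean"] <- wmean(dlum, w_bnd)
      out["bsa_lum_cv"] <- wcv(dlum, w_bnd)
    }
  }
  out
}

shannon <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log(p))
}

wmean <- function(x, w) {
  if (sum(w) == 0) return(0)
  sum(w * x) / sum(w)
}

wcv <- function(x, w) {
  m <- wmean(x, w)
  if (m <= 0 || sum(w) == 0) return(0)
  sqrt(wmean((x - m)^2, w)) / m
}

#' Extract the full metric row of one region of interest
#'
#' Runs the complete viewer-corrected chain on a cone-catch image: flooring,
#' acuity filtering, RNL segmentation, then the cluster, edge-intensity and
#' secondary statistics, returning one named 17-value metric row (3 cluster
#' + 2 edge + 12 secondary).
#'
#' @param img A [cone_image()].
#' @param viewer A [viewer_model()].
#' @param theta_color,theta_lum Segmentation thresholds in JND.
#' @param filter Apply the acuity filter first (default TRUE).
#' @return Named numeric vector of length 17.
#' @export
pattern_metrics <- function(img, viewer = viewer_model(),
                            theta_color = 3, theta_lum = 3,
                            filter = TRUE) {
  a <- floor_catches(unclass(img), viewer$floor_value)
  attributes(a) <- attributes(img)
  if (filter) a <- apply_acuity_filter(a, viewer)
  seg <- segment_rnl(a, viewer = viewer,
                     theta_color = theta_color, theta_lum = theta_lum)
  cs <- cluster_stats(seg)
  ed <- local_edge_intensity(a, viewer = viewer)
  c(n_clusters = cs$n_clusters,
    counts_within = cs$counts_within,
    area_largest = cs$area_largest,
    edge_color = ed$color_mean,
    edge_lum = ed$lum_mean,
    secondary_stats(seg, viewer))
}
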