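#' Local edge intensity
#'
#' Local edge contrast of the filtered (unsegmented) image: for every ROI
#' pixel, the chromatic and luminance RNL distances to its neighbour in each
#' of four directions (horizontal, vertical and the two diagonals; each
#' neighbour pair credits both of its pixels, so the result is invariant to
#' image rotation) are computed, the maximum over directions kept, and
#' the two metrics are the means of those per-pixel maxima over all ROI
#' pixels with at least one valid neighbour.
#'
#' @param img A [cone_image()] (filtered and floored).
#' @param roi Logical ROI mask; defaults to the image's own.
#' @param viewer A [viewer_model()].
#' @return A list: `color_mean` and `lum_mean`, both in JND.
#' @export
local_edge_intensity <- function(img, roi = attr(img, "roi"),
                                 viewer = viewer_model()) {
  a <- unclass(img)
  H <- dim(a)[1]; W <- dim(a)[2]
  if (is.null(roi)) roi <- matrix(TRUE, H, W)
  if (sum(roi) < 2L) stop("ROI must contain at least 2 pixels")
  flat <- matrix(a, H * W, 5L)
  if (any(flat[as.vector(roi), ] <= 0))
    stop("non-positive catches in ROI: apply floor_catches() first")

  dirs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  best_c <- matrix(-Inf, H, W)
  best_l <- matrix(-Inf, H, W)
  seen <- matrix(FALSE, H, W)
  for (d in dirs) {
    dr <- d[1L]; dc <- d[2L]
    rs <- seq_len(H - abs(dr))
    cs <- if (dc >= 0L) seq_len(W - dc) else seq(1L - dc, W)
    src <- as.matrix(expand.grid(r = rs, c = cs))
    dst <- cbind(src[, 1L] + dr, src[, 2L] + dc)
    i_src <- (src[, 2L] - 1L) * H + src[, 1L]
    i_dst <- (dst[, 2L] - 1L) * H + dst[, 1L]
    keep <- roi[i_src] & roi[i_dst]
    if (!any(keep)) next
    i_src <- i_src[keep]; i_dst <- i_dst[keep]
    dc_jnd <- rnl_chromatic_distance(flat[i_src, 1:4, drop = FALSE],
                                     flat[i_dst, 1:4, drop = FALSE], viewer)
    dl_jnd <- rnl_luminance_distance(flat[i_src, 5L], flat[i_dst, 5L], viewer)
    best_c[i_src] <- pmax(best_c[i_src], dc_jnd)
    best_l[i_src] <- pmax(best_l[i_src], dl_jnd)
    best_c[i_dst] <- pmax(best_c[i_dst], dc_jnd)
    best_l[i_dst] <- pmax(best_l[i_dst], dl_jnd)
    seen[i_src] <- TRUE
    seen[i_dst] <- TRUE
  }
  if (!any(seen)) stop("no ROI pixel has a valid neighbour")
  list(color_mean = mean(best_c[seen]), lum_mean = mean(best_l[seen]))
}
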