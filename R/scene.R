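#' Cone-catch image container
#'
#' A cone-catch image is an H x W x 5 array of non-negative photon catches,
#' one layer per receptor channel in the fixed order `LW, MW, SW, VS, DBL`,
#' with a physical scale in mm per pixel and an optional region-of-interest
#' mask.
#'
#' @param a Numeric H x W x 5 array.
#' @param mm_per_px Physical scale, mm per pixel.
#' @param roi Logical H x W mask; defaults to the full frame.
#' @return An object of class `cone_image` (the array, with attributes
#'   `mm_per_px` and `roi`).
#' @export
cone_image <- function(a, mm_per_px = 1, roi = NULL) {
  stopifnot(is.array(a), length(dim(a)) == 3L, dim(a)[3] == 5L,
            mm_per_px > 0)
  if (is.null(roi)) roi <- matrix(TRUE, dim(a)[1], dim(a)[2])
  stopifnot(is.logical(roi), all(dim(roi) == dim(a)[1:2]))
  structure(a, mm_per_px = mm_per_px, roi = roi, class = "cone_image")
}

#' @export
print.cone_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("cone_image %d x %d px (%.3g mm/px), 5 channels, %d ROI px\n",
              d[1], d[2], attr(x, "mm_per_px"), sum(attr(x, "roi"))))
  invisible(x)
}

#' Generate a planted-pattern cone-catch scene
#'
#' Builds a synthetic cone-catch image from a scene specification: a uniform
#' background colour with rectangular patches of known colour, area and
#' multiplicity planted at non-overlapping random positions. The returned
#' ground truth (label map, per-colour patch counts and areas) provides an
#' exact oracle for segmentation and cluster statistics.
#'
#' @param spec A list with elements `size` (c(H, W) px), `mm_per_px`,
#'   `background` (positive 5-vector of catches), and `patches`: a list of
#'   `list(catch = 5-vector, area = px, count = n)` entries. Patch catches
#'   must be positive.
#' @param seed Integer seed controlling patch placement.
#' @param noise_sd Optional i.i.d. Gaussian noise added per pixel/channel.
#' @param max_tries Placement retries per patch before giving up.
#' @return A list: `image` (a [cone_image()]), `truth` with `labels`
#'   (integer matrix, 0 = background), `colors` (matrix of planted catch
#'   vectors, row 1 = background), `patch_counts` and `areas_px` per planted
#'   colour.
#' @export
generate_scene <- function(spec, seed = 1L, noise_sd = 0, max_tries = 200L) {
  stopifnot(length(spec$size) == 2L, all(spec$size >= 2L),
            spec$mm_per_px > 0, length(spec$background) == 5L,
            all(spec$background > 0))
  for (p in spec$patches) {
    stopifnot(length(p$catch) == 5L, all(p$catch > 0),
              p$area >= 1, p$count >= 1)
  }
  set.seed(as.integer(seed))
  H <- spec$size[1]; W <- spec$size[2]
  labels <- matrix(0L, H, W)
  colors <- rbind(background = spec$background)
  counts <- integer(0)
  areas <- integer(0)
  lab <- 0L
  for (p in spec$patches) {
    lab <- lab + 1L
    colors <- rbind(colors, p$catch)
    # near-square rectangle of the requested area
    h <- max(1L, round(sqrt(p$area)))
    w <- max(1L, round(p$area / h))
    if (h > H || w > W) stop("patch larger than scene")
    placed <- 0L
    for (rep in seq_len(p$count)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        r0 <- sample.int(H - h + 1L, 1L)
        c0 <- sample.int(W - w + 1L, 1L)
        # 1-px clearance so distinct patches never touch
        rs <- max(1L, r0 - 1L):min(H, r0 + h)
        cs <- max(1L, c0 - 1L):min(W, c0 + w)
        if (all(labels[rs, cs] == 0L)) {
          labels[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- lab
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place patch without overlap; enlarge scene")
      placed <- placed + 1L
    }
    counts <- c(counts, placed)
    areas <- c(areas, h * w)
  }
  a <- array(0, dim = c(H, W, 5L))
  for (ch in 1:5) {
    plane <- matrix(spec$background[ch], H, W)
    if (lab > 0L) {
      for (l in seq_len(lab)) plane[labels == l] <- colors[l + 1L, ch]
    }
    if (noise_sd > 0) plane <- plane + stats::rnorm(H * W, 0, noise_sd)
    a[, , ch] <- plane
  }
  rownames(colors) <- NULL
  list(image = cone_image(a, mm_per_px = spec$mm_per_px),
       truth = list(labels = labels, colors = colors,
                    patch_counts = counts, areas_px = areas))
}

#' Write / read multilayer cone-catch TIFF images
#'
#' Images are stored as 5-layer 32-bit float TIFFs in channel order
#' `LW, MW, SW, VS, DBL`; the scale and an optional ground-truth record
#' travel in a JSON sidecar (`<path>.json`).
#'
#' @param img A [cone_image()].
#' @param path Output TIFF path.
#' @param truth Optional ground-truth list stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_cone_image <- function(img, path, truth = NULL) {
  layers <- lapply(1:5, function(ch) unclass(img)[, , ch])
  tiff::writeTIFF(layers, path, bits.per.sample = 32L, reduce = FALSE)
  side <- list(mm_per_px = attr(img, "mm_per_px"),
               channels = c("LW", "MW", "SW", "VS", "DBL"))
  if (!is.null(truth)) side$truth <- truth
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cone_image
#' @param roi Optional logical ROI matrix to attach on read.
#' @export
read_cone_image <- function(path, roi = NULL) {
  layers <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(layers) == 5L)
  a <- array(0, dim = c(dim(layers[[1]])[1:2], 5L))
  for (ch in 1:5) {
    l <- layers[[ch]]
    a[, , ch] <- if (length(dim(l)) == 3L) l[, , 1] else l
  }
  side_path <- paste0(path, ".json")
  mm <- 1
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$mm_per_px)) mm <- side$mm_per_px
  }
  cone_image(a, mm_per_px = mm, roi = roi)
}
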