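#' Connected-component labelling
#'
#' Labels connected regions of a logical mask (or of equal values of an
#' integer matrix, per value) by breadth-first flood fill.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels (0 where `mask` is FALSE).
#' @export
label_components <- function(mask, connectivity = 4L) {
  stopifnot(is.logical(mask), connectivity %in% c(4L, 8L))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  offs <- if (connectivity == 4L) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    cbind(rep(c(-1L, 0L, 1L), 3L), rep(c(-1L, 0L, 1L), each = 3L))[-5L, ]
  }
  nxt <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- integer(256L); queue[1L] <- start; qn <- 1L
    lab[start] <- nxt
    while (qn > 0L) {
      cur <- queue[qn]; qn <- qn - 1L
      r <- ((cur - 1L) %% H) + 1L
      cc <- ((cur - 1L) %/% H) + 1L
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1L]; ccc <- cc + offs[k, 2L]
        if (rr < 1L || rr > H || ccc < 1L || ccc > W) next
        idx <- (ccc - 1L) * H + rr
        if (mask[idx] && lab[idx] == 0L) {
          lab[idx] <- nxt
          qn <- qn + 1L
          if (qn > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[qn] <- idx
        }
      }
    }
  }
  lab
}

#' RNL agglomerative segmentation
#'
#' Segments the region of interest of a (filtered, floored) cone-catch image
#' into colour-pattern clusters using the observer's discrimination
#' thresholds. Two phases of agglomerative merging operate on region-mean
#' catches: first spatially adjacent regions merge while both the chromatic
#' and the luminance RNL distance between their means fall below the
#' thresholds; then remaining clusters merge globally (no adjacency
#' constraint) under the same rule, so that disjoint patches of
#' indistinguishable colour share one cluster label. Merging is
#' deterministic: the pair with the lowest combined distance
#' (`dc/theta_color + dl/theta_lum`) merges first, ties broken by lowest
#' label.
#'
#' @param img A [cone_image()] (ideally acuity-filtered and floored).
#' @param roi Logical ROI mask; defaults to the image's own.
#' @param viewer A [viewer_model()].
#' @param theta_color,theta_lum Merge thresholds in JND.
#' @return An object of class `segmented_pattern`: `labels` (integer matrix,
#'   NA outside the ROI, cluster ids 1..k), `means` (k x 5 cluster mean
#'   catches), `areas_px`, `areas_mm2`, `patch_counts` (4-connectivity),
#'   `adjacency` (k x k shared-boundary pixel-pair counts),
#'   `adjacency_h`/`adjacency_v` (horizontal / vertical transition counts)
#'   and `mm_per_px`.
#' @export
segment_rnl <- function(img, roi = attr(img, "roi"),
                        viewer = viewer_model(),
                        theta_color = 3, theta_lum = 3) {
  a <- unclass(img)
  H <- dim(a)[1]; W <- dim(a)[2]
  if (is.null(roi)) roi <- matrix(TRUE, H, W)
  npx <- sum(roi)
  if (npx == 0L) stop("empty ROI")
  if (any(a[, , ][rep(roi, 5L)] <= 0))
    stop("non-positive catches in ROI: apply floor_catches() first")
  mm <- attr(img, "mm_per_px")
  if (is.null(mm)) mm <- 1

  # initial regions: connected components of exactly-equal colour
  code <- matrix(match(
    apply(matrix(a, H * W, 5L), 1L, paste, collapse = "\r"),
    unique(apply(matrix(a, H * W, 5L), 1L, paste, collapse = "\r"))), H, W)
  region <- matrix(0L, H, W)
  nxt <- 0L
  for (cd in unique(code[roi])) {
    comp <- label_components(roi & code == cd, 4L)
    sel <- comp > 0L
    region[sel] <- comp[sel] + nxt
    nxt <- nxt + max(comp)
  }
  region[!roi] <- NA_integer_

  # region summaries
  k <- nxt
  sums <- matrix(0, k, 5L)
  flat <- matrix(a, H * W, 5L)
  rvec <- as.vector(region)
  inr <- !is.na(rvec)
  grp <- factor(rvec[inr], levels = seq_len(k))
  for (ch in 1:5)
    sums[, ch] <- as.vector(tapply(flat[inr, ch], grp, sum))
  sizes <- as.vector(table(grp))
  means <- sums / sizes

  # adjacency between initial regions (4-neighbour pixel pairs)
  pair_h <- region_pairs(region, 0L, 1L)   # horizontal neighbours
  pair_v <- region_pairs(region, 1L, 0L)   # vertical neighbours
  pairs <- rbind(pair_h, pair_v)
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  adj <- unique(pairs)

  alive <- rep(TRUE, k)
  parent <- seq_len(k)

  pair_dist <- function(adj) {
    # vectorised chromatic + luminance distances for an E x 2 pair table
    dc <- rnl_chromatic_distance(means[adj[, 1L], 1:4, drop = FALSE],
                                 means[adj[, 2L], 1:4, drop = FALSE],
                                 viewer)
    dl <- rnl_luminance_distance(means[adj[, 1L], 5L],
                                 means[adj[, 2L], 5L], viewer)
    cbind(dc, dl, dc / theta_color + dl / theta_lum)
  }

  merge_phase <- function(adj) {
    if (nrow(adj) == 0L) return(invisible(NULL))
    adj <- unique(cbind(pmin(adj[, 1L], adj[, 2L]),
                        pmax(adj[, 1L], adj[, 2L])))
    d <- pair_dist(adj)
    repeat {
      ok <- d[, 1L] < theta_color & d[, 2L] < theta_lum
      if (!any(ok)) break
      cand <- which(ok)
      best <- cand[order(d[cand, 3L], adj[cand, 1L], adj[cand, 2L])][1L]
      i <- adj[best, 1L]; j <- adj[best, 2L]
      # absorb j into i
      sums[i, ] <<- sums[i, ] + sums[j, ]
      sizes[i] <<- sizes[i] + sizes[j]
      means[i, ] <<- sums[i, ] / sizes[i]
      alive[j] <<- FALSE
      parent[parent == j] <<- i
      adj[adj == j] <- i
      keep <- adj[, 1L] != adj[, 2L]
      adj <- adj[keep, , drop = FALSE]
      d <- d[keep, , drop = FALSE]
      if (nrow(adj) == 0L) break
      adj <- cbind(pmin(adj[, 1L], adj[, 2L]), pmax(adj[, 1L], adj[, 2L]))
      dup <- duplicated(adj)
      adj <- adj[!dup, , drop = FALSE]
      d <- d[!dup, , drop = FALSE]
      touched <- which(adj[, 1L] == i | adj[, 2L] == i)
      if (length(touched) > 0L)
        d[touched, ] <- pair_dist(adj[touched, , drop = FALSE])
    }
    invisible(NULL)
  }

  merge_phase(adj)

  # global phase: all pairs of surviving clusters
  repeat {
    live <- which(alive)
    if (length(live) < 2L) break
    allp <- t(utils::combn(live, 2L))
    n_before <- sum(alive)
    merge_phase(allp)
    if (sum(alive) == n_before) break
  }

  # relabel 1..k in order of first appearance
  live <- which(alive)
  newid <- integer(k)
  newid[live] <- seq_along(live)
  labels <- matrix(NA_integer_, H, W)
  labels[inr] <- newid[parent[rvec[inr]]]

  k2 <- length(live)
  means2 <- means[live, , drop = FALSE]
  areas_px <- as.vector(table(factor(labels[roi], levels = seq_len(k2))))
  patch_counts <- vapply(seq_len(k2), function(l)
    max(label_components(!is.na(labels) & labels == l, 4L)), integer(1L))

  ph <- region_pairs(labels, 0L, 1L)
  pv <- region_pairs(labels, 1L, 0L)
  adj_h <- pair_count_matrix(ph, k2)
  adj_v <- pair_count_matrix(pv, k2)

  structure(list(labels = labels, means = means2,
                 areas_px = areas_px, areas_mm2 = areas_px * mm^2,
                 patch_counts = patch_counts,
                 adjacency = adj_h + adj_v,
                 adjacency_h = adj_h, adjacency_v = adj_v,
                 mm_per_px = mm),
            class = "segmented_pattern")
}

# neighbouring label pairs along an offset (dr, dc); drops NA
region_pairs <- function(lab, dr, dc) {
  H <- nrow(lab); W <- ncol(lab)
  r1 <- seq_len(H - dr); c1 <- seq_len(W - dc)
  a <- lab[r1, c1, drop = FALSE]
  b <- lab[r1 + dr, c1 + dc, drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  cbind(as.vector(a)[keep], as.vector(b)[keep])
}

# symmetric count matrix of differing-label neighbour pairs
pair_count_matrix <- function(pairs, k) {
  m <- matrix(0, k, k)
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs) > 0L) {
    i <- pmin(pairs[, 1L], pairs[, 2L])
    j <- pmax(pairs[, 1L], pairs[, 2L])
    tb <- table(paste(i, j))
    for (nm in names(tb)) {
      ij <- as.integer(strsplit(nm, " ")[[1L]])
      m[ij[1L], ij[2L]] <- m[ij[1L], ij[2L]] + tb[[nm]]
      m[ij[2L], ij[1L]] <- m[ij[1L], ij[2L]]
    }
  }
  m
}

#' @export
print.segmented_pattern <- function(x, ...) {
  cat(sprintf("segmented_pattern: %d clusters, %d patches, %d ROI px\n",
              nrow(x$means), sum(x$patch_counts), sum(x$areas_px)))
  invisible(x)
}

#' Cluster statistics of a segmented pattern
#'
#' The three cluster-component metrics: number of clusters, total number of
#' patches of the same cluster type summed over clusters (counts within
#' clusters), and the area of the largest cluster in mm^2.
#'
#' @param seg A [segment_rnl()] result.
#' @param connectivity Patch connectivity, 4 (default) or 8.
#' @return A list: `n_clusters`, `counts_within`, `area_largest`.
#' @export
cluster_stats <- function(seg, connectivity = 4L) {
  stopifnot(inherits(seg, "segmented_pattern"))
  k <- nrow(seg$means)
  counts <- if (connectivity == 4L) {
    sum(seg$patch_counts)
  } else {
    sum(vapply(seq_len(k), function(l)
      max(label_components(!is.na(seg$labels) & seg$labels == l,
                           connectivity)), integer(1L)))
  }
  list(n_clusters = k,
       counts_within = counts,
       area_largest = max(seg$areas_mm2))
}
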