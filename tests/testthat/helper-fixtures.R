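# shared fixture builders for the test suite

# a uniform 5-channel image
uniform_image <- function(h = 8, w = 8, value = 0.5, mm_per_px = 1) {
  cone_image(array(value, dim = c(h, w, 5L)), mm_per_px = mm_per_px)
}

# a two-region image split at row `split`, with distinct catches
step_image <- function(h = 4, w = 4, split = 2,
                       top = c(0.5, 0.5, 0.5, 0.5, 0.5),
                       bottom = c(0.5, 0.5, 0.5, 0.5, 0.5 * exp(0.1))) {
  a <- array(0, dim = c(h, w, 5L))
  for (ch in 1:5) {
    a[seq_len(split), , ch] <- top[ch]
    a[(split + 1):h, , ch] <- bottom[ch]
  }
  cone_image(a, mm_per_px = 1)
}

# small planted scene spec used across segmentation tests
planted_spec <- function() {
  list(size = c(40, 40), mm_per_px = 0.5,
       background = c(0.5, 0.5, 0.5, 0.5, 0.5),
       patches = list(
         list(catch = c(0.8, 0.3, 0.5, 0.5, 0.9), area = 25, count = 3),
         list(catch = c(0.2, 0.7, 0.5, 0.5, 0.2), area = 16, count = 1)))
}

# independent connected-component count via igraph (oracle route)
igraph_components <- function(mask, connectivity = 4) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(0L)
  id <- match(seq_len(H * W), idx)
  edges <- c()
  offs <- if (connectivity == 4) {
    list(c(0, 1), c(1, 0))
  } else {
    list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  }
  for (o in offs) {
    for (r in seq_len(H - o[1])) {
      cs <- if (o[2] >= 0) seq_len(W - o[2]) else seq(1 - o[2], W)
      for (cc in cs) {
        p <- (cc - 1) * H + r
        q <- (cc + o[2] - 1) * H + r + o[1]
        if (mask[p] && mask[q]) edges <- c(edges, id[p], id[q])
      }
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  igraph::components(g)$no
}

# brute-force Pearson chi-square on a 2 x k success/failure table
pearson_prop_chisq <- function(x, n) {
  p <- sum(x) / sum(n)
  O <- cbind(x, n - x)
  E <- cbind(n * p, n * (1 - p))
  sum((O - E)^2 / E)
}

# Monte-Carlo convex-hull volume via membership sampling in the
# bounding box; membership = point is within every facet half-space of
# the hull, checked by linear programming-free support test: a point is
# in the hull iff it cannot be separated, approximated here by testing
# against all facet planes of the (jitter-free) brute-force facet list.
mc_hull_volume <- function(P, n_samples = 1e5, seed = 1) {
  set.seed(seed)
  lo <- apply(P, 2, min); hi <- apply(P, 2, max)
  box <- prod(hi - lo)
  S <- cbind(runif(n_samples, lo[1], hi[1]),
             runif(n_samples, lo[2], hi[2]),
             runif(n_samples, lo[3], hi[3]))
  inside <- rep(TRUE, n_samples)
  m <- nrow(P)
  ctr <- colMeans(P)
  for (i in 1:(m - 2)) for (j in (i + 1):(m - 1)) for (k in (j + 1):m) {
    u <- P[j, ] - P[i, ]; v <- P[k, ] - P[i, ]
    nrm <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    if (sum(nrm^2) < 1e-18) next
    s <- P %*% nrm - sum(nrm * P[i, ])
    if (all(s <= 1e-12) || all(s >= -1e-12)) {
      # orient outward (away from centroid)
      if (sum(nrm * ctr) - sum(nrm * P[i, ]) > 0) nrm <- -nrm
      inside <- inside & (S %*% nrm - sum(nrm * P[i, ]) <= 1e-12)
    }
  }
  box * mean(inside)
}
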