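test_that("acuity blur size follows small-angle trigonometry", {
  v <- viewer_model(acuity = 41, viewing_distance = 5000)
  # independent oracle: object-plane extent of a 1/41 degree angle at 5 m
  oracle <- 2 * 5000 * tan((1 / 41) * pi / 180 / 2)
  expect_equal(acuity_fwhm_mm(v), 2.128, tolerance = 1e-3)
  expect_equal(acuity_fwhm_mm(v), oracle, tolerance = 1e-6)
})

test_that("acuity filtering preserves constants, means and impulse mass", {
  v <- viewer_model()
  u <- uniform_image(16, 16, 0.37, mm_per_px = 0.25)
  f <- apply_acuity_filter(u, v)
  expect_equal(as.vector(unclass(f)), as.vector(unclass(u)), tolerance = 1e-12)

  set.seed(4)
  a <- array(runif(16 * 16 * 5, 0.2, 0.8), dim = c(16, 16, 5))
  img <- cone_image(a, mm_per_px = 0.25)
  fi <- apply_acuity_filter(img, v)
  for (ch in 1:5)
    expect_equal(mean(unclass(fi)[, , ch]), mean(a[, , ch]),
                 tolerance = 1e-6)

  imp <- array(0, dim = c(21, 21, 5)); imp[11, 11, ] <- 1
  fi <- apply_acuity_filter(cone_image(imp, mm_per_px = 0.25), v)
  for (ch in 1:5) expect_equal(sum(unclass(fi)[, , ch]), 1, tolerance = 1e-6)

  # sub-pixel kernel: identity with warning
  coarse <- uniform_image(8, 8, 0.5, mm_per_px = 10)
  expect_warning(out <- apply_acuity_filter(coarse, v), "unchanged")
  expect_identical(unclass(out), unclass(coarse))
})

test_that("catch flooring replaces only non-positive values", {
  expect_equal(floor_catches(c(-0.2, 0, 0.5, 1e-6)),
               c(0.001, 0.001, 0.5, 1e-6))
  expect_equal(floor_catches(rep(-1, 5)), rep(0.001, 5))
})

test_that("RNL chromatic distance matches closed forms and invariances", {
  v <- viewer_model()
  expect_equal(rnl_chromatic_distance(c(1, 1, 1, 1), c(1, 1, 1, 1), v), 0)
  # dichromat reduction: delta-log (0.1, 0), e = (0.05, 0.05)
  d2 <- rnl_chromatic_distance(c(exp(0.1), 1), c(1, 1), v)
  expect_equal(d2, 0.1 / sqrt(2 * 0.05^2), tolerance = 1e-12)
  expect_equal(d2, 1.4142, tolerance = 1e-4)
  # symmetry and scale invariance
  a <- c(0.8, 0.3, 0.5, 0.6); b <- c(0.4, 0.7, 0.5, 0.2)
  expect_equal(rnl_chromatic_distance(a, b, v),
               rnl_chromatic_distance(b, a, v))
  expect_equal(rnl_chromatic_distance(10 * a, 10 * b, v),
               rnl_chromatic_distance(a, b, v), tolerance = 1e-12)
  expect_error(rnl_chromatic_distance(c(-1, 1, 1, 1), b, v), "floor")
})

test_that("RNL luminance distance matches its closed form", {
  v <- viewer_model(weber_luminance = 0.05)
  expect_equal(rnl_luminance_distance(1, 1, v), 0)
  expect_equal(rnl_luminance_distance(exp(0.05), 1, v), 1, tolerance = 1e-12)
  expect_equal(rnl_luminance_distance(2, 5, v),
               rnl_luminance_distance(5, 2, v))
  expect_error(rnl_luminance_distance(0, 1, v), "floor")
})

test_that("segmentation recovers planted patterns and merges alike regions", {
  v <- viewer_model()
  seg_u <- segment_rnl(uniform_image(10, 10, 0.5), viewer = v)
  expect_equal(nrow(seg_u$means), 1L)
  expect_equal(seg_u$areas_px, 100L)

  sc <- generate_scene(planted_spec(), seed = 7)
  seg <- segment_rnl(sc$image, viewer = v)
  expect_equal(nrow(seg$means), 3L)  # background + two planted colours
  expect_setequal(seg$areas_px,
                  c(40 * 40 - 3 * 25 - 16, 3 * 25, 16))

  # two regions below both thresholds merge to one cluster
  im <- step_image(6, 6, 3,
                   top = c(0.5, 0.5, 0.5, 0.5, 0.5),
                   bottom = c(0.5 * exp(0.004), 0.5, 0.5, 0.5,
                              0.5 * exp(0.004)))
  seg2 <- segment_rnl(im, viewer = v, theta_color = 3, theta_lum = 3)
  expect_equal(nrow(seg2$means), 1L)

  expect_error(segment_rnl(uniform_image(4, 4),
                           roi = matrix(FALSE, 4, 4)), "empty")
})

test_that("segmented-pattern structure satisfies its invariants", {
  v <- viewer_model()
  sc <- generate_scene(planted_spec(), seed = 13)
  seg <- segment_rnl(sc$image, viewer = v)
  expect_equal(sum(seg$areas_px), sum(attr(sc$image, "roi")))
  expect_true(isSymmetric(seg$adjacency))
  expect_true(all(diag(seg$adjacency) == 0))
  expect_equal(seg$adjacency, seg$adjacency_h + seg$adjacency_v)
})

test_that("cluster statistics agree with an independent component oracle", {
  skip_if_not_installed("igraph")
  v <- viewer_model()
  sc <- generate_scene(planted_spec(), seed = 7)
  seg <- segment_rnl(sc$image, viewer = v)
  cs <- cluster_stats(seg)
  expect_equal(cs$n_clusters, 3L)
  oracle <- sum(vapply(seq_len(3), function(l)
    igraph_components(!is.na(seg$labels) & seg$labels == l, 4), numeric(1)))
  expect_equal(cs$counts_within, as.integer(oracle))
  expect_equal(cs$counts_within, 5L)  # 3 + 1 patches + background
  expect_equal(cs$area_largest, max(seg$areas_px) * 0.5^2)

  u <- segment_rnl(uniform_image(10, 10, 0.5, mm_per_px = 2), viewer = v)
  cu <- cluster_stats(u)
  expect_equal(cu$n_clusters, 1L)
  expect_equal(cu$counts_within, 1L)
  expect_equal(cu$area_largest, 100 * 4)
})

test_that("checkerboard patch counts follow the enumeration formula", {
  # k x k checkerboard of two colours: every cell its own 4-connected patch
  k <- 6
  a <- array(0.5, dim = c(k, k, 5))
  chk <- outer(seq_len(k), seq_len(k), function(r, c) (r + c) %% 2 == 0)
  a[, , 1][chk] <- 0.9
  a[, , 5][chk] <- 0.9
  seg <- segment_rnl(cone_image(a), viewer = viewer_model())
  cs <- cluster_stats(seg, connectivity = 4)
  expect_equal(cs$n_clusters, 2L)
  expect_equal(cs$counts_within, k * k)
  # with 8-connectivity the two colours are single patches
  cs8 <- cluster_stats(seg, connectivity = 8)
  expect_equal(cs8$counts_within, 2L)
})

test_that("edge intensity matches a hand count and is rotation invariant", {
  v <- viewer_model()
  expect_equal(local_edge_intensity(uniform_image(6, 6, 0.5), viewer = v),
               list(color_mean = 0, lum_mean = 0))

  # 4 x 4 ROI, luminance step of 2 JND between rows 2 and 3:
  # the 8 pixels in rows 2-3 see the step (max = 2), the other 8 see 0
  im <- step_image(4, 4, 2,
                   top = c(0.5, 0.5, 0.5, 0.5, 0.5),
                   bottom = c(0.5, 0.5, 0.5, 0.5, 0.5 * exp(0.1)))
  ed <- local_edge_intensity(im, viewer = v)
  expect_equal(ed$lum_mean, 2 * 8 / 16, tolerance = 1e-9)
  expect_equal(ed$color_mean, 0, tolerance = 1e-9)

  # same step rotated 90 degrees: identical metrics
  a <- unclass(im)
  rot <- array(0, dim = c(4, 4, 5))
  for (ch in 1:5) rot[, , ch] <- t(a[4:1, , ch])
  ed_rot <- local_edge_intensity(cone_image(rot), viewer = v)
  expect_equal(ed_rot$lum_mean, ed$lum_mean, tolerance = 1e-12)
  expect_equal(ed_rot$color_mean, ed$color_mean, tolerance = 1e-12)

  expect_error(local_edge_intensity(uniform_image(1, 1)), "2 pixels")
})

test_that("acuity filtering never increases step-edge intensity", {
  v <- viewer_model()
  im <- step_image(12, 12, 6,
                   top = c(0.6, 0.4, 0.5, 0.5, 0.7),
                   bottom = c(0.3, 0.7, 0.5, 0.5, 0.3))
  attr(im, "mm_per_px") <- 0.5
  before <- local_edge_intensity(im, viewer = v)
  after <- local_edge_intensity(apply_acuity_filter(im, v), viewer = v)
  expect_lte(after$color_mean, before$color_mean)
  expect_lte(after$lum_mean, before$lum_mean)
})

test_that("secondary statistics match closed forms", {
  v <- viewer_model()
  seg_u <- segment_rnl(uniform_image(8, 8, 0.5), viewer = v)
  s <- secondary_stats(seg_u, v)
  expect_length(s, 12L)
  expect_named(s, secondary_stat_names())
  expect_equal(unname(s["caa_div"]), 0)
  expect_equal(unname(s["caa_even"]), 1)
  expect_equal(unname(s["caa_hv_ratio"]), 1)
  expect_true(all(s[grep("mean|cv|trans", names(s))] == 0))

  # two equal-area clusters: area diversity ln 2
  im <- step_image(8, 8, 4,
                   top = c(0.9, 0.3, 0.5, 0.5, 0.9),
                   bottom = c(0.2, 0.8, 0.5, 0.5, 0.2))
  seg <- segment_rnl(im, viewer = v)
  s2 <- secondary_stats(seg, v)
  expect_equal(nrow(seg$means), 2L)
  expect_equal(unname(s2["caa_div"]), log(2), tolerance = 1e-12)
  expect_equal(unname(s2["caa_even"]), 1, tolerance = 1e-12)
  # single boundary pair: contrasts equal the pair distances, CVs 0
  dcol <- rnl_chromatic_distance(seg$means[1, 1:4], seg$means[2, 1:4], v)
  dlum <- rnl_luminance_distance(seg$means[1, 5], seg$means[2, 5], v)
  expect_equal(unname(s2["vca_col_mean"]), dcol)
  expect_equal(unname(s2["bsa_lum_mean"]), dlum)
  expect_equal(unname(s2["vca_col_cv"]), 0)
  # horizontal step between rows -> all transitions vertical
  expect_equal(unname(s2["caa_hv_ratio"]), (0 + 1) / (8 + 1))
})

test_that("the metric chain is deterministic", {
  v <- viewer_model()
  sc <- generate_scene(planted_spec(), seed = 3, noise_sd = 0.01)
  m1 <- pattern_metrics(sc$image, v)
  m2 <- pattern_metrics(sc$image, v)
  expect_identical(m1, m2)
  expect_length(m1, 17L)
})

test_that("cone images round-trip through multilayer TIFF", {
  sc <- generate_scene(planted_spec(), seed = 2)
  path <- tempfile(fileext = ".tif")
  write_cone_image(sc$image, path, truth = list(n_colors = 3))
  back <- read_cone_image(path)
  expect_equal(dim(unclass(back)), dim(unclass(sc$image)))
  expect_equal(as.vector(unclass(back)), as.vector(unclass(sc$image)),
               tolerance = 1e-6)
  expect_equal(attr(back, "mm_per_px"), 0.5)
})
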