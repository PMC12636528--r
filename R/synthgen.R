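#' Names of the per-ROI metric columns
#'
#' Three cluster metrics, two edge-intensity metrics, then the twelve
#' secondary statistics of [secondary_stat_names()].
#'
#' @return Character vector of length 17.
#' @export
metric_names <- function() {
  c("n_clusters", "counts_within", "area_largest",
    "edge_color", "edge_lum", secondary_stat_names())
}

#' Study design of a synthetic field survey
#'
#' Describes the sampling structure of a multi-location lizard survey: how
#' many lizards, at which locations, which genetic clade and habitat class
#' each location belongs to, how many background options are photographed
#' per lizard and how many background images are lost to file corruption.
#' The defaults emulate a 52-lizard, 7-location, 4-clade design with 6
#' backgrounds per lizard (one of them the occupied perch) and 3 corrupted
#' background images, i.e. 309 usable background rows.
#'
#' @param n_lizards Total number of lizards.
#' @param locations Character vector of location names.
#' @param clade_of_location Named character vector mapping every location to
#'   one clade.
#' @param habitat_of_location Named character vector mapping every location
#'   to one habitat class.
#' @param lizards_per_location Integer vector (same order as `locations`)
#'   summing to `n_lizards`.
#' @param backgrounds_per_lizard Background options photographed per lizard
#'   (>= 2), perch included.
#' @param n_corrupted Background images lost to corruption (never a perch).
#' @param svl_range Snout-vent-length range (mm) for the uniform SVL draw.
#' @return An object of class `study_design`.
#' @examples
#' d <- study_design()
#' d$n_lizards * d$backgrounds_per_lizard - d$n_corrupted  # 309
#' @export
study_design <- function(n_lizards = 52L,
                         locations = c("Werrikimbe", "Gibraltar",
                                       "Wyrrabalong", "Warrumbungles",
                                       "Murramarang", "Croajingalong",
                                       "YouYangs"),
                         clade_of_location = c(Werrikimbe = "A",
                                               Gibraltar = "A",
                                               Wyrrabalong = "B",
                                               Warrumbungles = "C",
                                               Murramarang = "C",
                                               Croajingalong = "C",
                                               YouYangs = "D"),
                         habitat_of_location = c(Werrikimbe = "other",
                                                 Gibraltar = "other",
                                                 Wyrrabalong = "coastal heath",
                                                 Warrumbungles = "other",
                                                 Murramarang = "coastal heath",
                                                 Croajingalong = "coastal heath",
                                                 YouYangs = "other"),
                         lizards_per_location = NULL,
                         backgrounds_per_lizard = 6L,
                         n_corrupted = 3L,
                         svl_range = c(60, 120)) {
  if (backgrounds_per_lizard < 2L)
    stop("backgrounds_per_lizard must be >= 2")
  if (!setequal(names(clade_of_location), locations) ||
      !setequal(names(habitat_of_location), locations))
    stop("every location needs exactly one clade and one habitat")
  total_bg <- n_lizards * backgrounds_per_lizard
  if (n_corrupted >= total_bg)
    stop("n_corrupted must be smaller than the total number of backgrounds")
  if (n_corrupted > n_lizards * (backgrounds_per_lizard - 1L))
    stop("n_corrupted exceeds the number of removable (non-perch) backgrounds")
  if (is.null(lizards_per_location)) {
    base <- n_lizards %/% length(locations)
    lizards_per_location <- rep(base, length(locations))
    extra <- n_lizards - sum(lizards_per_location)
    if (extra > 0)
      lizards_per_location[seq_len(extra)] <-
        lizards_per_location[seq_len(extra)] + 1L
    # the default 52/7 design mirrors the field sampling: clade totals
    # A 16, B 6, C 25, D 5
    if (n_lizards == 52L && length(locations) == 7L)
      lizards_per_location <- c(8L, 8L, 6L, 8L, 8L, 9L, 5L)
  }
  if (sum(lizards_per_location) != n_lizards)
    stop("lizards_per_location must sum to n_lizards")
  structure(list(n_lizards = as.integer(n_lizards),
                 locations = locations,
                 clade_of_location = clade_of_location[locations],
                 habitat_of_location = habitat_of_location[locations],
                 lizards_per_location = as.integer(lizards_per_location),
                 backgrounds_per_lizard = as.integer(backgrounds_per_lizard),
                 n_corrupted = as.integer(n_corrupted),
                 svl_range = svl_range),
            class = "study_design")
}

#' Effect specification for the synthetic generator
#'
#' Defines the generative model for metric rows. A lizard's 17-metric row is
#' multivariate normal around a group mean (base mean plus additive clade /
#' sex / habitat offsets); each of its background rows is
#' `lizard + s * offset0 + v * scatter_j`, where `offset0` is a common
#' microhabitat displacement (scale `s`, the mismatch scale, governs how far
#' the microhabitat sits from the lizard's own pattern) and `scatter_j` is a
#' per-option displacement (scale `v`, the scatter scale, governs
#' background-option diversity and perch-to-optimal distances).
#' Group-specific multipliers on `s` and `v` and a log-linear SVL trend on
#' `v` plant recoverable effects; a `shifted_location` moves one location's
#' backgrounds away from its own lizards so that between-location distances
#' undercut within-location ones there.
#'
#' @param mean Named base mean (length 17, [metric_names()]).
#' @param sd Named between-lizard SDs (length 17).
#' @param secondary_loadings 12 x 3 matrix of latent loadings giving the
#'   secondary statistics a 3-factor correlation structure (so the visual
#'   PCA has supported components); NULL for independent noise.
#' @param bg_center_sd,bg_scatter_sd SDs (same 17 metric units) of the
#'   microhabitat displacement and per-option scatter draws.
#' @param mismatch_rules,scatter_rules Lists of
#'   `list(clade =, sex =, habitat =, mult =)` rules; omitted factors match
#'   anything, all matching rules multiply.
#' @param svl_scatter_slope Log-scale slope of `v` per mm SVL about the
#'   mid-range.
#' @param perch_rule `"random"` (perch is a random option), `"optimal"`
#'   (the perch duplicates the lizard's own metric row, hence is the closest
#'   background in every component space) or `"kth_closest"`.
#' @param perch_k Rank used by `"kth_closest"` (2 = second closest).
#' @param shifted_location Optional list `list(location =, shift =)` adding
#'   a constant displacement (in units of `sd`) to that location's
#'   background rows.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(mean = NULL, sd = NULL,
                        secondary_loadings = NULL,
                        bg_center_sd = 0.8, bg_scatter_sd = 0.6,
                        mismatch_rules = list(),
                        scatter_rules = list(),
                        svl_scatter_slope = 0,
                        perch_rule = c("random", "optimal", "kth_closest"),
                        perch_k = 2L,
                        shifted_location = NULL) {
  nm <- metric_names()
  default_mean <- stats::setNames(
    c(6, 25, 300, 2, 2.5,
      1.2, 0.7, 1.0, 1.0, 3, 0.4, 3, 0.4, 3, 0.4, 3, 0.4), nm)
  default_sd <- stats::setNames(
    c(1.5, 6, 80, 0.5, 0.6,
      0.25, 0.1, 0.25, 0.15, 0.7, 0.1, 0.7, 0.1, 0.7, 0.1, 0.7, 0.1), nm)
  if (is.null(mean)) mean <- default_mean
  if (is.null(sd)) sd <- default_sd
  stopifnot(length(mean) == 17L, length(sd) == 17L, all(sd > 0),
            bg_center_sd >= 0, bg_scatter_sd >= 0)
  names(mean) <- nm; names(sd) <- nm
  if (is.null(secondary_loadings)) {
    # three latent factors loading on the CAA / VCA / BSA families
    L <- matrix(0, 12L, 3L)
    L[1:4, 1L] <- c(1, 0.8, 0.9, 0.3)
    L[5:8, 2L] <- c(1, 0.4, 0.9, 0.3)
    L[9:12, 3L] <- c(1, 0.4, 0.9, 0.3)
    secondary_loadings <- L
  }
  stopifnot(all(dim(secondary_loadings) == c(12L, 3L)))
  perch_rule <- match.arg(perch_rule)
  structure(list(mean = mean, sd = sd,
                 secondary_loadings = secondary_loadings,
                 bg_center_sd = bg_center_sd,
                 bg_scatter_sd = bg_scatter_sd,
                 mismatch_rules = mismatch_rules,
                 scatter_rules = scatter_rules,
                 svl_scatter_slope = svl_scatter_slope,
                 perch_rule = perch_rule,
                 perch_k = as.integer(perch_k),
                 shifted_location = shifted_location,
                 clade_offsets = list(), sex_offsets = list(),
                 habitat_offsets = list()),
            class = "effect_spec")
}

rule_multiplier <- function(rules, clade, sex, habitat) {
  m <- 1
  for (r in rules) {
    if (!is.null(r$clade) && r$clade != clade) next
    if (!is.null(r$sex) && r$sex != sex) next
    if (!is.null(r$habitat) && r$habitat != habitat) next
    m <- m * r$mult
  }
  m
}

# floors keeping metric rows in their natural ranges
floor_metrics <- function(m) {
  m["n_clusters"] <- max(1, round(m["n_clusters"]))
  m["counts_within"] <- max(m["n_clusters"], round(m["counts_within"]))
  m["area_largest"] <- max(1, m["area_largest"])
  m["edge_color"] <- max(0.01, m["edge_color"])
  m["edge_lum"] <- max(0.01, m["edge_lum"])
  m["caa_div"] <- max(0, m["caa_div"])
  m["caa_even"] <- min(1, max(0, m["caa_even"]))
  m["caa_trans_div"] <- max(0, m["caa_trans_div"])
  m["caa_hv_ratio"] <- max(0.05, m["caa_hv_ratio"])
  for (v in c("vca_col_mean", "vca_lum_mean", "bsa_col_mean",
              "bsa_lum_mean"))
    m[v] <- max(0.01, m[v])
  for (v in c("vca_col_cv", "vca_lum_cv", "bsa_col_cv", "bsa_lum_cv"))
    m[v] <- max(0, m[v])
  m
}

#' Generate a study-structured synthetic dataset
#'
#' Draws a complete synthetic survey: one dorsal-pattern metric row per
#' lizard and one per background option, with factors (location, clade,
#' habitat, sex, SVL), perch flags, and `n_corrupted` non-perch background
#' rows marked missing. Identical seeds reproduce the dataset exactly.
#'
#' @param design A [study_design()].
#' @param effects An [effect_spec()].
#' @param seed Integer seed.
#' @return An object of class `study_dataset`: a list with `table` (one
#'   data.frame row per ROI), `design`, `effects` and `seed`.
#' @examples
#' ds <- generate_study(seed = 1)
#' sum(ds$table$role == "background" & !ds$table$missing)  # 309
#' @export
generate_study <- function(design = study_design(),
                           effects = effect_spec(), seed = 1L) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_spec"))
  set.seed(as.integer(seed))
  nm <- metric_names()
  nb <- design$backgrounds_per_lizard
  mid_svl <- mean(design$svl_range)
  rows <- vector("list", design$n_lizards * (nb + 1L))
  ri <- 0L
  liz <- 0L
  for (li in seq_along(design$locations)) {
    loc <- design$locations[li]
    clade <- design$clade_of_location[[loc]]
    habitat <- design$habitat_of_location[[loc]]
    for (ii in seq_len(design$lizards_per_location[li])) {
      liz <- liz + 1L
      lizard_id <- sprintf("L%03d", liz)
      sex <- if (stats::runif(1) < 0.5) "female" else "male"
      svl <- stats::runif(1, design$svl_range[1], design$svl_range[2])
      mu <- effects$mean
      for (off in list(effects$clade_offsets[[clade]],
                       effects$sex_offsets[[sex]],
                       effects$habitat_offsets[[habitat]]))
        if (!is.null(off)) mu[names(off)] <- mu[names(off)] + off
      z <- stats::rnorm(3L)
      lat <- as.vector(effects$secondary_loadings %*% z)
      m_liz <- mu + effects$sd * stats::rnorm(17L)
      m_liz[6:17] <- m_liz[6:17] + effects$sd[6:17] * lat
      m_liz <- floor_metrics(stats::setNames(m_liz, nm))

      s <- rule_multiplier(effects$mismatch_rules, clade, sex, habitat)
      v <- rule_multiplier(effects$scatter_rules, clade, sex, habitat) *
        exp(effects$svl_scatter_slope * (svl - mid_svl))
      offset0 <- effects$bg_center_sd * effects$sd * stats::rnorm(17L)
      loc_shift <- numeric(17L)
      if (!is.null(effects$shifted_location) &&
          identical(effects$shifted_location$location, loc))
        loc_shift <- effects$shifted_location$shift * effects$sd

      bgs <- matrix(0, nb, 17L, dimnames = list(NULL, nm))
      for (b in seq_len(nb)) {
        scatter <- effects$bg_scatter_sd * effects$sd * stats::rnorm(17L)
        bgs[b, ] <- floor_metrics(stats::setNames(
          m_liz + s * offset0 + v * scatter + loc_shift, nm))
      }
      perch_idx <- switch(effects$perch_rule,
        random = sample.int(nb, 1L),
        optimal = {
          bgs[1L, ] <- m_liz
          1L
        },
        kth_closest = {
          dmat <- sweep(bgs, 2L, effects$sd, "/")
          lz <- m_liz / effects$sd
          d <- sqrt(rowSums(sweep(dmat, 2L, lz, "-")^2))
          order(d)[min(effects$perch_k, nb)]
        })

      ri <- ri + 1L
      rows[[ri]] <- data.frame(roi_id = lizard_id, lizard_id = lizard_id,
                               location = loc, clade = clade,
                               habitat = habitat, sex = sex, svl = svl,
                               role = "lizard", is_perch = FALSE,
                               missing = FALSE,
                               t(m_liz), check.names = FALSE)
      for (b in seq_len(nb)) {
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          roi_id = sprintf("%s_B%d", lizard_id, b),
          lizard_id = lizard_id, location = loc, clade = clade,
          habitat = habitat, sex = sex, svl = svl,
          role = "background", is_perch = b == perch_idx,
          missing = FALSE, t(bgs[b, ]), check.names = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ds <- structure(list(table = tab, design = design, effects = effects,
                       seed = as.integer(seed)),
                  class = "study_dataset")
  if (design$n_corrupted > 0L)
    ds <- corrupt_backgrounds(ds, design$n_corrupted, seed = seed + 1L)
  ds
}

#' @export
print.study_dataset <- function(x, ...) {
  t <- x$table
  cat(sprintf(paste0("study_dataset: %d lizards, %d usable backgrounds",
                     " (%d corrupted), %d locations, seed %d\n"),
              sum(t$role == "lizard"),
              sum(t$role == "background" & !t$missing),
              sum(t$missing), length(unique(t$location)), x$seed))
  invisible(x)
}

#' Mark background images lost to file corruption
#'
#' Randomly flags `n` non-perch background rows as missing, emulating image
#' files lost in the field pipeline. Perches are never removed, so every
#' microhabitat keeps its perch and at least one alternative.
#'
#' @param dataset A [generate_study()] result.
#' @param n Number of backgrounds to remove.
#' @param seed Integer seed.
#' @return The dataset with `n` additional rows flagged `missing`.
#' @export
corrupt_backgrounds <- function(dataset, n, seed = 1L) {
  stopifnot(inherits(dataset, "study_dataset"), n >= 0L)
  if (n == 0L) return(dataset)
  t <- dataset$table
  removable <- which(t$role == "background" & !t$is_perch & !t$missing)
  # keep >= 1 alternative per lizard: never take a lizard's last non-perch
  if (n > length(removable))
    stop("n exceeds the number of removable non-perch backgrounds")
  set.seed(as.integer(seed))
  picked <- integer(0)
  pool <- removable
  for (i in seq_len(n)) {
    counts <- table(t$lizard_id[pool])
    ok <- pool[counts[t$lizard_id[pool]] > 1L]
    if (length(ok) == 0L) ok <- pool
    pick <- if (length(ok) == 1L) ok else sample(ok, 1L)
    picked <- c(picked, pick)
    pool <- setdiff(pool, pick)
  }
  t$missing[picked] <- TRUE
  dataset$table <- t
  dataset
}
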