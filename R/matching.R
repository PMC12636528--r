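#' Lizard-to-background distances within one microhabitat
#'
#' Euclidean distances between a lizard's component vector and each of its
#' available background options in one component space.
#'
#' @param lizard_vec Numeric vector (the lizard's coordinates).
#' @param background_vecs Matrix of background coordinates (rownames are
#'   background ids) or a single vector.
#' @param space Label stored with the records (`"cluster"`, `"edge"`,
#'   `"visual"`).
#' @param is_perch Logical vector flagging the perch row.
#' @param lizard_id Identifier stored with the records.
#' @return A data.frame of distance records: `lizard_id`, `background_id`,
#'   `space`, `d`, `is_perch`.
#' @export
microhabitat_distances <- function(lizard_vec, background_vecs,
                                   space = "cluster",
                                   is_perch = NULL, lizard_id = "L001") {
  B <- rbind(background_vecs)
  if (is.matrix(background_vecs)) B <- background_vecs
  if (ncol(B) != length(lizard_vec))
    stop("dimension mismatch between lizard and background vectors")
  if (nrow(B) < 1L) stop("at least one background is required")
  if (is.null(is_perch)) is_perch <- rep(FALSE, nrow(B))
  stopifnot(length(is_perch) == nrow(B))
  ids <- rownames(B)
  if (is.null(ids)) ids <- sprintf("B%d", seq_len(nrow(B)))
  d <- sqrt(colSums((t(B) - lizard_vec)^2))
  data.frame(lizard_id = lizard_id, background_id = ids, space = space,
             d = unname(d), is_perch = is_perch,
             stringsAsFactors = FALSE)
}

#' Identify the optimal background of a microhabitat
#'
#' The optimal background is the option with the smallest distance to the
#' lizard. Ties are broken by the lowest background id (and flagged). When
#' the lizard is not on the optimal background, the distance between the
#' perch and the optimal background is computed from their coordinate
#' vectors.
#'
#' @param records Distance records from [microhabitat_distances()] (one
#'   lizard, one space; >= 2 backgrounds, exactly one perch).
#' @param background_vecs Matrix of background coordinates with rownames
#'   matching `background_id`; needed for `d_perch_to_optimal`.
#' @return A one-row data.frame: `lizard_id`, `space`,
#'   `optimal_background_id`, `on_optimal`, `tied`, `d_lizard_perch`,
#'   `d_lizard_optimal`, `d_perch_to_optimal` (NA when on the optimal).
#' @export
find_optimal <- function(records, background_vecs = NULL) {
  stopifnot(nrow(records) >= 2L, sum(records$is_perch) == 1L)
  if (all(is.na(records$d))) stop("all background distances are missing")
  ord <- order(records$d, records$background_id)
  best <- ord[1L]
  tied <- sum(records$d == records$d[best]) > 1L
  on_optimal <- records$is_perch[best]
  perch <- which(records$is_perch)
  d_po <- NA_real_
  if (!on_optimal && !is.null(background_vecs)) {
    pv <- background_vecs[records$background_id[perch], ]
    ov <- background_vecs[records$background_id[best], ]
    d_po <- sqrt(sum((pv - ov)^2))
  }
  data.frame(lizard_id = records$lizard_id[1L],
             space = records$space[1L],
             optimal_background_id = records$background_id[best],
             on_optimal = on_optimal, tied = tied,
             d_lizard_perch = records$d[perch],
             d_lizard_optimal = records$d[best],
             d_perch_to_optimal = d_po,
             stringsAsFactors = FALSE)
}

#' Per-microhabitat matching analysis of a whole dataset
#'
#' For every lizard and every component space, computes the distance records
#' to its own (usable) backgrounds and the optimal-background call.
#'
#' @param spaces A [build_component_spaces()] result.
#' @return A list: `distances` (all per-microhabitat distance records) and
#'   `optimal` (one row per lizard per space, with the lizard's factors
#'   joined on).
#' @export
matching_analysis <- function(spaces) {
  stopifnot(inherits(spaces, "component_spaces"))
  meta <- spaces$meta
  liz_rows <- which(meta$role == "lizard")
  recs <- list(); opts <- list()
  for (sp in names(spaces$spaces)) {
    M <- spaces$spaces[[sp]]
    for (i in liz_rows) {
      lid <- meta$lizard_id[i]
      brow <- which(meta$role == "background" & meta$lizard_id == lid)
      B <- M[brow, , drop = FALSE]
      rownames(B) <- meta$roi_id[brow]
      r <- microhabitat_distances(M[i, ], B, space = sp,
                                  is_perch = meta$is_perch[brow],
                                  lizard_id = lid)
      recs[[length(recs) + 1L]] <- r
      opts[[length(opts) + 1L]] <- find_optimal(r, B)
    }
  }
  distances <- do.call(rbind, recs)
  optimal <- do.call(rbind, opts)
  fac <- unique(meta[meta$role == "lizard",
                     c("lizard_id", "location", "clade", "habitat",
                       "sex", "svl")])
  optimal <- merge(optimal, fac, by = "lizard_id", sort = FALSE)
  list(distances = distances, optimal = optimal)
}

#' Test equality of on-optimal proportions across clades
#'
#' Pearson k-sample test of equal proportions (no continuity correction for
#' more than two groups), as a k x 2 chi-square test with k - 1 degrees of
#' freedom.
#'
#' @param successes Named vector of on-optimal counts per clade.
#' @param totals Named vector of lizards per clade (same order).
#' @return A list: `statistic`, `df`, `p.value`, `proportions`.
#' @examples
#' proportion_test_by_clade(c(A = 3, B = 2, C = 0, D = 0),
#'                          c(A = 16, B = 6, C = 25, D = 5))
#' @export
proportion_test_by_clade <- function(successes, totals) {
  stopifnot(length(successes) == length(totals), all(totals >= 0),
            all(successes <= totals))
  keep <- totals > 0
  if (!all(keep)) {
    warning("dropping clade(s) with zero total: ",
            paste(names(totals)[!keep], collapse = ", "))
    successes <- successes[keep]; totals <- totals[keep]
  }
  if (length(totals) < 2L) stop("need at least two clades with lizards")
  if (sum(successes) == 0L || sum(successes) == sum(totals)) {
    # degenerate margin: all proportions equal (0 or 1), statistic 0
    return(list(statistic = 0, df = length(totals) - 1L, p.value = 1,
                proportions = unname(successes / totals)))
  }
  ht <- suppressWarnings(stats::prop.test(successes, totals, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, proportions = unname(ht$estimate))
}
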