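#' Interaction GLM with the Type I / II / III decision rule
#'
#' Fits a Gaussian-family GLM of a (possibly transformed) response on sex,
#' habitat, clade and SVL with the interaction terms sex x habitat and
#' sex x clade, and applies the sums-of-squares decision rule: interaction
#' terms are tested first by sequential (Type I) deviance chi-square tests;
#' if at least one interaction is significant at `alpha`, non-significant
#' interactions are removed and main effects are tested by Type III
#' chi-squares under sum-to-zero contrasts; otherwise all interactions are
#' removed and main effects are tested by Type II chi-squares.
#'
#' @param table Data.frame with columns `sex`, `habitat`, `clade`, `svl`
#'   and the response.
#' @param response Name of the response column.
#' @param transform `"identity"`, `"log10"` or `"sqrt"`; log10 requires a
#'   strictly positive response.
#' @param alpha Significance level of the interaction screen.
#' @return An object of class `matching_glm`: `term_table` (Terms, SS type,
#'   Df, statistic, residual Df/deviance for Type I rows, p-value), the
#'   fitted `model` used for the main-effect tests, `full_model`,
#'   `ss_type`, `significant_interactions`, `aliased` flags, `response`,
#'   `transform`.
#' @export
fit_matching_glm <- function(table, response,
                             transform = c("identity", "log10", "sqrt"),
                             alpha = 0.05) {
  transform <- match.arg(transform)
  req <- c("sex", "habitat", "clade", "svl", response)
  miss <- setdiff(req, names(table))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  d <- table[stats::complete.cases(table[, req]), req, drop = FALSE]
  y <- d[[response]]
  if (transform == "log10") {
    if (any(y <= 0)) stop("log10 transform requires a positive response")
    d$.y <- log10(y)
  } else if (transform == "sqrt") {
    if (any(y < 0)) stop("sqrt transform requires a non-negative response")
    d$.y <- sqrt(y)
  } else d$.y <- y
  for (f in c("sex", "habitat", "clade")) d[[f]] <- factor(d[[f]])

  # flag empty sex x clade / sex x habitat cells rather than dropping
  aliased <- c(
    sex_habitat = any(table(d$sex, d$habitat) == 0L),
    sex_clade = any(table(d$sex, d$clade) == 0L))

  full <- stats::glm(.y ~ sex + habitat + clade + svl +
                       sex:habitat + sex:clade,
                     family = stats::gaussian(), data = d)
  a1 <- stats::anova(full, test = "Chisq")
  int_terms <- c("sex:habitat", "sex:clade")
  p_int <- stats::setNames(a1[int_terms, "Pr(>Chi)"], int_terms)
  sig <- !is.na(p_int) & p_int < alpha

  main_terms <- c("sex", "habitat", "clade", "svl")
  if (any(sig)) {
    ss_type <- 3L
    keep <- int_terms[sig]
    form <- stats::reformulate(c(main_terms, keep), response = ".y")
    ctr <- list(sex = "contr.sum", habitat = "contr.sum",
                clade = "contr.sum")
    mod <- stats::glm(form, family = stats::gaussian(), data = d,
                      contrasts = ctr)
    an <- car::Anova(mod, type = 3, test.statistic = "LR")
  } else {
    ss_type <- 2L
    mod <- stats::glm(.y ~ sex + habitat + clade + svl,
                      family = stats::gaussian(), data = d)
    an <- car::Anova(mod, type = 2, test.statistic = "LR")
  }

  rows <- list()
  for (tm in main_terms) {
    rows[[tm]] <- data.frame(
      term = tm, ss_type = as.character(ss_type),
      df = an[tm, "Df"], statistic = an[tm, "LR Chisq"],
      resid_df = NA_real_, resid_dev = NA_real_,
      p_value = an[tm, "Pr(>Chisq)"])
  }
  for (tm in int_terms) {
    rows[[tm]] <- data.frame(
      term = tm, ss_type = "1",
      df = a1[tm, "Df"], statistic = a1[tm, "Deviance"],
      resid_df = a1[tm, "Resid. Df"], resid_dev = a1[tm, "Resid. Dev"],
      p_value = a1[tm, "Pr(>Chi)"])
  }
  term_table <- do.call(rbind, rows)
  rownames(term_table) <- NULL
  structure(list(term_table = term_table, model = mod, full_model = full,
                 ss_type = ss_type,
                 significant_interactions = int_terms[sig],
                 interaction_p = p_int, aliased = aliased,
                 response = response, transform = transform,
                 alpha = alpha, data = d),
            class = "matching_glm")
}

#' @export
print.matching_glm <- function(x, ...) {
  cat(sprintf("GLM of %s (%s transform): Type %s main effects\n",
              x$response, x$transform,
              c("I", "II", "III")[x$ss_type]))
  if (length(x$significant_interactions) > 0)
    cat("  significant interaction(s):",
        paste(x$significant_interactions, collapse = ", "), "\n")
  print(x$term_table, digits = 4)
  invisible(x)
}

#' Estimated marginal means and pairwise contrasts
#'
#' Predictions at each factor combination averaged over the remaining
#' factors with SVL at its mean, with 95% confidence intervals, and
#' pairwise contrasts within a conditioning factor with multiplicity
#' adjustment (Holm by default).
#'
#' @param glm_fit A [fit_matching_glm()] (or [fit_diversity_glm()]) result.
#' @param specs An emmeans specification, e.g. `~ clade | sex`.
#' @param adjust Adjustment method passed to [emmeans::contrast()].
#' @return A list: `emmeans` (estimates with 95% CIs) and `contrasts`
#'   (pairwise contrasts with adjusted p-values), both data.frames.
#' @export
emm_and_contrasts <- function(glm_fit, specs = ~ clade | sex,
                              adjust = "holm") {
  stopifnot(inherits(glm_fit, "matching_glm"))
  em <- emmeans::emmeans(glm_fit$model, specs, data = glm_fit$data)
  ct <- emmeans::contrast(em, method = "pairwise", adjust = adjust)
  list(emmeans = as.data.frame(stats::confint(em)),
       contrasts = as.data.frame(ct))
}
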