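# Random-intercept linear mixed models fitted by REML, with containment
# denominator degrees of freedom, marginal F tests on fixed effects, and
# Tukey-adjusted pairwise contrasts on the levels of a fixed factor.
#
# The REML fit itself is delegated to lme4 (the numerical engine); estimation
# targets, the containment df rule, F statistics and the studentized-range
# adjustment are implemented here, so inference matches the nlme/emmeans-style
# workflow this field uses.

#' Specify a random-intercept mixed model
#'
#' @param response Response column name.
#' @param fixed_effects Character vector of fixed-effect column names
#'   (continuous or categorical).
#' @param random_intercepts Character vector of grouping columns, outermost
#'   first; more than one entry means nesting (e.g. cell within animal).
#' @return A `mixed_model_spec` list.
#' @export
mixed_model_spec <- function(response, fixed_effects, random_intercepts) {
  stopifnot(is.character(response), length(response) == 1L,
            is.character(fixed_effects), length(fixed_effects) >= 1L,
            is.character(random_intercepts), length(random_intercepts) >= 1L)
  structure(list(response = response, fixed_effects = fixed_effects,
                 random_intercepts = random_intercepts),
            class = "mixed_model_spec")
}

#' Fit a random-intercept linear mixed model by REML
#'
#' @param data A data.frame with complete cases for all model columns.
#' @param spec A [mixed_model_spec()].
#' @return An `lmm_fit`: fixed-effect estimates and SEs, variance components
#'   (one per random term plus residual), REML log-likelihood, grouping sizes,
#'   and internals used by [anova_fixed_effects()] and [pairwise_tukey()].
#' @export
fit_lmm_reml <- function(data, spec) {
  stopifnot(inherits(spec, "mixed_model_spec"), is.data.frame(data))
  fx <- setdiff(spec$fixed_effects, "1")     # "1" = intercept-only model
  cols <- c(spec$response, fx, spec$random_intercepts)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stopf("columns missing from data: %s", paste(miss, collapse = ", "))
  data <- data[stats::complete.cases(data[, cols]), cols, drop = FALSE]
  for (g in spec$random_intercepts) {
    data[[g]] <- factor(data[[g]])
    if (nlevels(data[[g]]) < 2L)
      stopf("random grouping '%s' needs at least 2 groups", g)
  }
  for (f in fx)
    if (is.character(data[[f]])) data[[f]] <- factor(data[[f]])

  # nested grouping: animal, then cell-within-animal coded animal:cell
  grp_terms <- spec$random_intercepts[1]
  if (length(spec$random_intercepts) > 1L) {
    for (i in 2:length(spec$random_intercepts)) {
      nm <- paste(spec$random_intercepts[seq_len(i)], collapse = ".")
      data[[nm]] <- interaction(data[, spec$random_intercepts[seq_len(i)]],
                                drop = TRUE)
      grp_terms <- c(grp_terms, nm)
    }
  }
  fixed_rhs <- if (length(fx)) paste(fx, collapse = " + ") else "1"
  ran_rhs <- paste(sprintf("(1 | %s)", grp_terms), collapse = " + ")
  fml <- stats::as.formula(paste(spec$response, "~", fixed_rhs, "+", ran_rhs))

  fit <- lme4::lmer(fml, data = data, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  X <- lme4::getME(fit, "X")
  if (qr(X)$rank < ncol(X)) stopf("fixed-effect design is rank deficient")
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vcomp <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual", vc$grp))

  tl <- attr(stats::terms(stats::as.formula(paste(spec$response, "~", fixed_rhs)),
                          data = data), "term.labels")
  asg <- attr(X, "assign")
  group_sizes <- vapply(grp_terms, function(g) nlevels(data[[g]]), integer(1))

  out <- list(beta = beta, se = sqrt(diag(V)), vcov = V,
              varcomp = vcomp, logLik_reml = as.numeric(stats::logLik(fit)),
              n = nrow(data), term_labels = tl, assign = asg,
              X = X, data = data, spec = spec, grp_terms = grp_terms,
              group_sizes = group_sizes,
              fixed_formula = stats::as.formula(paste("~", fixed_rhs)),
              converged = length(fit@optinfo$conv$lme4) == 0L,
              engine_fit = fit)
  class(out) <- "lmm_fit"
  out
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept LMM (REML)\n")
  cat(sprintf("  n = %d; groups: %s\n", x$n,
              paste(sprintf("%s (%d)", x$grp_terms, x$group_sizes), collapse = ", ")))
  est <- data.frame(estimate = x$beta, se = x$se)
  print(round(est, 4))
  cat("Variance components:\n")
  print(round(x$varcomp, 5))
  invisible(x)
}

# Containment denominator df, nlme-style. Levels: 1..Q are the grouping
# levels outermost -> innermost, level Q+1 the observations. A fixed term is
# assigned to the outermost level within whose groups it varies; denominator
# df at level l is m_l - (m_{l-1} + p_l) with m_0 = 1 and p_l the number of
# fixed-effect columns estimated at that level. The intercept sits at the
# innermost level.
containment_df <- function(fit) {
  data <- fit$data
  Q <- length(fit$grp_terms)
  m <- c(1L, fit$group_sizes, fit$n)          # m_0 .. m_{Q+1}
  X <- fit$X
  ncolX <- ncol(X)
  # a column constant within level-l groups (but varying between them) is
  # estimated at level l; one varying within even the innermost groups is
  # estimated at the observation level Q+1; the intercept sits at Q+1.
  col_level <- integer(ncolX)
  for (j in seq_len(ncolX)) {
    if (fit$assign[j] == 0L) { col_level[j] <- Q + 1L; next }  # intercept
    lev <- NA_integer_
    for (l in seq_len(Q)) {
      varies <- any(tapply(X[, j], data[[fit$grp_terms[l]]],
                           function(v) max(v) - min(v) > 1e-10))
      if (!varies) { lev <- l; break }
    }
    col_level[j] <- if (is.na(lev)) Q + 1L else lev
  }
  p_at <- tabulate(col_level, nbins = Q + 1L)
  df_at <- m[seq_len(Q + 1L) + 1L] - (m[seq_len(Q + 1L)] + p_at)
  term_level <- vapply(seq_along(fit$term_labels), function(k) {
    cols <- which(fit$assign == k)
    max(col_level[cols])
  }, integer(1))
  list(col_level = col_level, term_level = term_level,
       df_at = pmax(df_at, 1L), p_at = p_at)
}

#' Marginal F tests on fixed effects
#'
#' Wald F statistics per fixed-effect term with containment denominator df.
#'
#' @param fit An [fit_lmm_reml()] result.
#' @param ddf `"containment"` (default) or `"residual"` (n - p).
#' @return data.frame: term, numerator df, denominator df, F, p.
#' @export
anova_fixed_effects <- function(fit, ddf = c("containment", "residual")) {
  stopifnot(inherits(fit, "lmm_fit"))
  ddf <- match.arg(ddf)
  cdf <- containment_df(fit)
  out <- lapply(seq_along(fit$term_labels), function(k) {
    cols <- which(fit$assign == k)
    if (!length(cols)) return(NULL)
    b <- fit$beta[cols]
    Vk <- fit$vcov[cols, cols, drop = FALSE]
    q <- length(cols)
    Fstat <- as.numeric(t(b) %*% solve(Vk, b)) / q
    den <- if (ddf == "containment") cdf$df_at[cdf$term_level[k]]
           else fit$n - length(fit$beta)
    if (q == 1L && is.factor(fit$data[[fit$term_labels[k]]]) &&
        nlevels(fit$data[[fit$term_labels[k]]]) < 2L)
      stopf("factor '%s' has a single level", fit$term_labels[k])
    data.frame(term = fit$term_labels[k], num_df = q, den_df = den,
               F = Fstat, p = stats::pf(Fstat, q, den, lower.tail = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Tukey-adjusted pairwise comparisons of a fixed factor's levels
#'
#' Estimated marginal means are formed by averaging model-matrix rows with the
#' factor forced to each level in turn (other covariates kept at their
#' observed values); all pairwise differences are tested with the studentized
#' range adjustment at the factor's containment df.
#'
#' @param fit An [fit_lmm_reml()] result.
#' @param factor_name Name of a categorical fixed effect in the model.
#' @return data.frame: contrast, estimate, se, t, df, p_adjusted.
#' @export
pairwise_tukey <- function(fit, factor_name) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!(factor_name %in% fit$term_labels))
    stopf("'%s' is not a fixed effect of the model", factor_name)
  fac <- fit$data[[factor_name]]
  if (!is.factor(fac)) stopf("'%s' is not categorical", factor_name)
  levs <- levels(fac)
  k <- length(levs)
  if (k < 2L) stopf("factor '%s' has a single level", factor_name)
  trm <- stats::delete.response(stats::terms(fit$fixed_formula, data = fit$data))
  rows <- vapply(levs, function(l) {
    nd <- fit$data
    nd[[factor_name]] <- factor(l, levels = levs)
    colMeans(stats::model.matrix(trm, nd))
  }, numeric(ncol(fit$X)))
  cdf <- containment_df(fit)
  df <- cdf$df_at[cdf$term_level[match(factor_name, fit$term_labels)]]
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    cvec <- rows[, ij[1]] - rows[, ij[2]]
    est <- sum(cvec * fit$beta)
    se <- sqrt(as.numeric(t(cvec) %*% fit$vcov %*% cvec))
    tstat <- est / se
    p <- stats::ptukey(sqrt(2) * abs(tstat), nmeans = k, df = df,
                       lower.tail = FALSE)
    data.frame(contrast = paste(levs[ij[1]], "-", levs[ij[2]]),
               estimate = est, se = se, t = tstat, df = df, p_adjusted = p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
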