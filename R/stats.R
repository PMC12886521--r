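#' Nested group comparison of a response parameter
#'
#' Compares groups on one response parameter while respecting the hierarchy
#' of the design: penetrating arterioles (observations) are nested within
#' mice (independent units), so inference runs on mouse-level error, never on
#' pooled arterioles. The model is a two-level linear mixed model with a
#' random mouse intercept, fitted by REML with Satterthwaite degrees of
#' freedom (via `lmerTest`). With a single two-level factor the result is the
#' nested t-test; with more levels or two factors an omnibus F-test is
#' reported together with Tukey-adjusted pairwise comparisons on model-based
#' marginal means (via `emmeans`).
#'
#' When every mouse's arterioles carry identical values the residual level of
#' the model is unidentifiable; the fit then reduces exactly — not
#' approximately — to the analysis of mouse means, and that closed form is
#' used: a pooled-variance t-test on mouse means for two groups, a one-way
#' ANOVA on mouse means otherwise.
#'
#' @param table A metric table: one row per arteriole (x timepoint) with at
#'   least `mouse_id` and the requested factor and metric columns.
#' @param metric Name of the metric column to analyze.
#' @param factors Character vector of fixed-effect factor columns (e.g.
#'   `"group"`, or `c("group", "sex")`). The first factor defines the
#'   pairwise comparisons.
#' @return An object of class `nested_test`; see [tidy.nested_test()] and
#'   [glance.nested_test()]. Fields include the effect estimate and its SE
#'   (two-group case), mouse-level df, test statistic, `p_value`, variance
#'   components (`var_mouse`, `var_resid`), an `omnibus` tibble and a
#'   `pairwise` tibble.
#' @examples
#' s <- generate_session(session_design(n_mice_per_group = 4, seed = 2),
#'                       render = FALSE)
#' nested_compare(s$truth, "t_max_s", "group")
#' @export
nested_compare <- function(table, metric, factors = "group") {
  stopifnot(is.data.frame(table), metric %in% names(table),
            all(factors %in% names(table)), "mouse_id" %in% names(table))
  df <- as_tibble(table)
  df$.y <- df[[metric]]
  df <- df[is.finite(df$.y), ]
  for (f in factors) df[[f]] <- factor(df[[f]])
  df$mouse_id <- factor(df$mouse_id)

  # each mouse must sit in exactly one cell of the first factor,
  # and every level needs >= 2 mice for a between-mouse variance
  n_mice <- tapply(df$mouse_id, df[[factors[1]]],
                   function(m) length(unique(m)))
  if (any(n_mice < 2)) {
    abort(sprintf("level(s) %s of '%s' have a single mouse; between-mouse variance is not estimable",
                  paste(names(n_mice)[n_mice < 2], collapse = ", "), factors[1]))
  }

  within_ss <- sum(tapply(df$.y, df$mouse_id,
                          function(v) sum((v - mean(v))^2)))
  scale2 <- mean(df$.y^2) + 1e-300
  degenerate <- within_ss / scale2 < 1e-24

  if (degenerate && length(factors) == 1) {
    res <- nested_mouse_means(df, factors[1])
  } else {
    res <- nested_lmm(df, factors)
  }
  res$metric <- metric
  res$factors <- factors
  res$n_pa <- nrow(df)
  res$n_mice <- length(unique(df$mouse_id))
  class(res) <- "nested_test"
  res
}

# Exact reduction when arterioles are constant within every mouse: analyze
# mouse means with ordinary fixed-effects machinery.
nested_mouse_means <- function(df, factor1) {
  mm <- dplyr::summarise(
    dplyr::group_by(df, .data$mouse_id, .g = .data[[factor1]]),
    .y = mean(.data$.y), .groups = "drop"
  )
  lev <- levels(mm$.g)
  k <- length(lev)
  n <- tapply(mm$.y, mm$.g, length)
  means <- tapply(mm$.y, mm$.g, mean)
  ss_within <- sum(tapply(mm$.y, mm$.g, function(v) sum((v - mean(v))^2)))
  df_err <- nrow(mm) - k
  ms_err <- ss_within / df_err
  if (k == 2) {
    est <- unname(means[2] - means[1])
    se <- sqrt(ms_err * (1 / n[1] + 1 / n[2]))
    tstat <- est / se
    p <- 2 * stats::pt(-abs(tstat), df_err)
    omnibus <- tibble(term = factor1, statistic = tstat^2, df1 = 1,
                      df2 = df_err, p_value = p)
    pairwise <- tibble(contrast = paste(lev[2], "-", lev[1]),
                       estimate = est, se = se, df = df_err,
                       statistic = tstat, p_adj = p)
    list(method = "mouse-means t-test (exact degenerate reduction)",
         estimate = est, se = unname(se), df = df_err,
         statistic = unname(tstat), p_value = unname(p),
         var_mouse = unname(ms_err), var_resid = 0,
         omnibus = omnibus, pairwise = pairwise, model = NULL)
  } else {
    ss_between <- sum(n * (means - mean(mm$.y))^2)
    fstat <- (ss_between / (k - 1)) / ms_err
    p <- stats::pf(fstat, k - 1, df_err, lower.tail = FALSE)
    prs <- utils::combn(k, 2)
    pw <- lapply(seq_len(ncol(prs)), function(j) {
      i1 <- prs[1, j]; i2 <- prs[2, j]
      est <- means[i2] - means[i1]
      se <- sqrt(ms_err * (1 / n[i1] + 1 / n[i2]))
      # studentized range on mouse-level error df
      q <- abs(est) / sqrt(ms_err / 2 * (1 / n[i1] + 1 / n[i2]))
      tibble(contrast = paste(lev[i2], "-", lev[i1]),
             estimate = unname(est), se = unname(se), df = df_err,
             statistic = unname(est / se),
             p_adj = unname(stats::ptukey(q, k, df_err, lower.tail = FALSE)))
    })
    omnibus <- tibble(term = factor1, statistic = fstat, df1 = k - 1,
                      df2 = df_err, p_value = p)
    list(method = "mouse-means ANOVA (exact degenerate reduction)",
         estimate = NA_real_, se = NA_real_, df = df_err,
         statistic = unname(fstat), p_value = unname(p),
         var_mouse = unname(ms_err), var_resid = 0,
         omnibus = omnibus, pairwise = dplyr::bind_rows(pw), model = NULL)
  }
}

nested_lmm <- function(df, factors) {
  fml <- stats::reformulate(c(factors, "(1 | mouse_id)"), response = ".y")
  fit <- suppressMessages(
    lmerTest::lmer(fml, data = df, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_mouse <- vc$vcov[vc$grp == "mouse_id"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  an <- as.data.frame(stats::anova(fit, type = 2))
  omnibus <- tibble(
    term = rownames(an), statistic = an[["F value"]],
    df1 = an[["NumDF"]], df2 = an[["DenDF"]], p_value = an[["Pr(>F)"]]
  )
  k <- nlevels(df[[factors[1]]])
  two_group <- k == 2 && length(factors) == 1
  if (two_group) {
    co <- stats::coef(summary(fit))
    est <- co[2, "Estimate"]; se <- co[2, "Std. Error"]
    dfree <- co[2, "df"]; tstat <- co[2, "t value"]; p <- co[2, "Pr(>|t|)"]
    lev <- levels(df[[factors[1]]])
    pairwise <- tibble(
      contrast = paste(lev[2], "-", lev[1]), estimate = est, se = se,
      df = dfree, statistic = tstat, p_adj = p
    )
  } else {
    est <- NA_real_; se <- NA_real_
    dfree <- omnibus$df2[1]; tstat <- omnibus$statistic[1]
    p <- omnibus$p_value[1]
    emm <- emmeans::emmeans(fit, specs = factors[1],
                            lmer.df = "satterthwaite")
    pw <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                          adjust = "tukey"))
    pairwise <- tibble(
      contrast = as.character(pw$contrast), estimate = pw$estimate,
      se = pw$SE, df = pw$df, statistic = pw$t.ratio, p_adj = pw$p.value
    )
  }
  list(method = "linear mixed model, random mouse intercept (REML, Satterthwaite df)",
       estimate = unname(est), se = unname(se), df = unname(dfree),
       statistic = unname(tstat), p_value = unname(p),
       var_mouse = var_mouse, var_resid = var_resid,
       omnibus = omnibus, pairwise = pairwise, model = fit)
}

#' @exportS3Method base::print
print.nested_test <- function(x, ...) {
  cat(sprintf("<nested_test> %s ~ %s  (%d PAs, %d mice)\n", x$metric,
              paste(x$factors, collapse = " + "), x$n_pa, x$n_mice))
  cat("  method:", x$method, "\n")
  if (is.finite(x$estimate)) {
    cat(sprintf("  estimate %.4g (SE %.4g), t(%.2f) = %.3f, p = %.4g\n",
                x$estimate, x$se, x$df, x$statistic, x$p_value))
  } else {
    cat(sprintf("  omnibus F(%g, %.2f) = %.3f, p = %.4g\n",
                x$omnibus$df1[1], x$omnibus$df2[1], x$statistic, x$p_value))
  }
  cat(sprintf("  variance: between-mouse %.4g, within-mouse %.4g\n",
              x$var_mouse, x$var_resid))
  invisible(x)
}

#' Tidy a nested test
#'
#' @param x A [nested_compare()] result.
#' @param effects `"pairwise"` (default) or `"omnibus"`.
#' @param ... Unused.
#' @return A tibble of contrasts or omnibus terms.
#' @export
tidy.nested_test <- function(x, effects = c("pairwise", "omnibus"), ...) {
  effects <- match.arg(effects)
  if (effects == "pairwise") x$pairwise else x$omnibus
}

#' One-row summary of a nested test
#'
#' @param x A [nested_compare()] result.
#' @param ... Unused.
#' @export
glance.nested_test <- function(x, ...) {
  tibble(
    metric = x$metric, method = x$method,
    estimate = x$estimate, se = x$se, df = x$df,
    statistic = x$statistic, p_value = x$p_value,
    var_mouse = x$var_mouse, var_resid = x$var_resid,
    n_pa = x$n_pa, n_mice = x$n_mice
  )
}

#' Pearson correlation with best linear fit
#'
#' Pearson's r between two metric columns with the two-sided p-value from the
#' t transform and the least-squares line, as used to relate response
#' parameters to basal diameter or glucose measures.
#'
#' @param data A data frame.
#' @param x,y Column names (strings) of the two variables.
#' @return A one-row tibble: `r`, `p_value`, `n`, `slope`, `intercept`.
#' @export
pearson_corr <- function(data, x, y) {
  xs <- data[[x]]; ys <- data[[y]]
  keep <- is.finite(xs) & is.finite(ys)
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) < 3) abort("need at least 3 complete observations")
  if (sd(xs) == 0 || sd(ys) == 0) abort("zero variance; correlation undefined")
  ct <- stats::cor.test(xs, ys, method = "pearson")
  fit <- stats::lm(ys ~ xs)
  tibble(
    r = unname(ct$estimate),
    p_value = ct$p.value,
    n = length(xs),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1])
  )
}

#' Mouse-level summary of a metric
#'
#' Aggregates arteriole-level values to one record per mouse (and timepoint,
#' when present), the unit at which group statistics are reported as
#' mean ± SD.
#'
#' @param table A metric table with `mouse_id` (and optionally `group`,
#'   `timepoint`).
#' @param metric Metric column name.
#' @return A tibble with `mean`, `sd` (0 with `single_pa = TRUE` when a mouse
#'   contributed one arteriole) and `n_pa` per mouse.
#' @export
summarize_by_mouse <- function(table, metric) {
  stopifnot(metric %in% names(table), "mouse_id" %in% names(table))
  keys <- intersect(c("group", "timepoint", "mouse_id"), names(table))
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::as_tibble(table),
                    dplyr::across(dplyr::all_of(keys))),
    mean = mean(.data[[metric]]),
    sd = stats::sd(.data[[metric]]),
    n_pa = dplyr::n(),
    .groups = "drop"
  )
  out$single_pa <- out$n_pa == 1L
  out$sd[out$single_pa] <- 0
  out
}
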