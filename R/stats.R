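# Statistical layer: paired/independent comparisons, exact Wilcoxon
# signed-rank, mixed two-way ANOVA with partial eta squared and simple
# effects, multiplicity correction, and change-score correlation matrices.
# All p-values are two-sided.

.stat_row <- function(test, statistic, df, p_value, estimate = NA_real_,
                      effect_size = NA_real_, method = NA_character_) {
  tibble(test = test, statistic = unname(statistic), df = unname(df),
         p_value = unname(p_value), estimate = unname(estimate),
         effect_size = unname(effect_size), method = method)
}

#' Paired t-test (post vs pre)
#'
#' Two-sided paired t-test of `post - pre` with `n - 1` degrees of freedom;
#' a positive statistic means the scores increased. `estimate` is the mean
#' change and `effect_size` is Cohen's dz (mean change over SD of changes).
#'
#' @param pre,post Equal-length numeric vectors, paired by position, `n >= 2`.
#' @return A one-row tibble: `test`, `statistic`, `df`, `p_value`,
#'   `estimate`, `effect_size`, `method`.
#' @export
#' @examples
#' scores <- clinical_scores()
#' paired_t(scores$fma_ue_pre, scores$fma_ue_post) # t = 4.357, df = 19
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) abort("`pre` and `post` lengths differ.")
  if (length(pre) < 2L) abort("Need n >= 2 pairs.")
  d <- post - pre
  if (stats::var(d) == 0) {
    abort("Degenerate data: all paired differences are equal (zero variance).")
  }
  fit <- stats::t.test(post, pre, paired = TRUE)
  .stat_row("paired_t", fit$statistic, fit$parameter, fit$p.value,
            estimate = mean(d), effect_size = mean(d) / stats::sd(d),
            method = "two-sided paired t")
}

#' Independent-samples t-test
#'
#' Two-sided two-sample t-test of `group1 - group2`; pooled variance by
#' default, Welch's unequal-variance form when `welch = TRUE`. `estimate` is
#' the mean difference and `effect_size` Cohen's d (pooled SD).
#'
#' @param group1,group2 Numeric vectors, each with `n >= 2`.
#' @param welch Use the Welch correction.
#' @return A one-row tibble as in [paired_t()].
#' @export
independent_t <- function(group1, group2, welch = FALSE) {
  if (length(group1) < 2L || length(group2) < 2L) {
    abort("Each group needs n >= 2.")
  }
  if (!welch && stats::var(group1) == 0 && stats::var(group2) == 0) {
    abort("Degenerate data: zero pooled variance.")
  }
  fit <- stats::t.test(group1, group2, var.equal = !welch)
  n1 <- length(group1); n2 <- length(group2)
  sp <- sqrt(((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) /
               (n1 + n2 - 2))
  .stat_row("independent_t", fit$statistic, fit$parameter, fit$p.value,
            estimate = mean(group1) - mean(group2),
            effect_size = if (sp > 0) (mean(group1) - mean(group2)) / sp else NA_real_,
            method = if (welch) "two-sided Welch t" else "two-sided pooled-variance t")
}

# Exact null distribution of the signed-rank statistic for (possibly tied)
# ranks, via the generating function over sign patterns. Ranks are doubled so
# midranks become integers; returns P(W2 = w) for w = 0..sum(2*ranks).
.signrank_exact_pmf <- function(ranks2) {
  total <- sum(ranks2)
  pmf <- numeric(total + 1L)
  pmf[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), pmf[seq_len(total + 1L - r)])
    pmf <- (pmf + shifted) / 2
  }
  pmf
}

#' Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of `post - pre`. Zero differences are dropped.
#' For `n <= 25` non-zero differences the p-value is exact, computed from the
#' full enumeration of sign patterns (handled by a generating-function
#' recursion that also accommodates tied ranks); for larger `n` a normal
#' approximation with tie-corrected variance is used. The statistic is the
#' sum of ranks of positive differences.
#'
#' @param pre,post Equal-length numeric vectors, paired by position.
#' @param exact_max Largest `n` for which the exact distribution is used.
#' @return A one-row tibble as in [paired_t()]; `estimate` is the median
#'   change.
#' @export
wilcoxon_signed_rank <- function(pre, post, exact_max = 25) {
  if (length(pre) != length(post)) abort("`pre` and `post` lengths differ.")
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) abort("All paired differences are zero.")
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_max) {
    pmf <- .signrank_exact_pmf(as.integer(round(2 * rk)))
    w2 <- as.integer(round(2 * V))
    p_low <- sum(pmf[seq_len(w2 + 1L)])
    p_high <- sum(pmf[seq.int(w2 + 1L, length(pmf))])
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact two-sided signed rank"
  } else {
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approximation two-sided signed rank"
  }
  .stat_row("wilcoxon_signed_rank", V, NA_real_, p,
            estimate = stats::median(post - pre), method = method)
}

#' Pearson correlation with two-sided p-value
#'
#' Pearson's r with the usual t transform on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors, `n >= 3`, both with positive variance.
#' @return A one-row tibble; `estimate` holds r.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` lengths differ.")
  if (length(x) < 3L) abort("Need n >= 3.")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("Zero variance: correlation undefined.")
  }
  fit <- stats::cor.test(x, y, method = "pearson")
  .stat_row("pearson_corr", fit$statistic, fit$parameter, fit$p.value,
            estimate = unname(fit$estimate), method = "two-sided Pearson r")
}

#' Multiplicity correction
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up false discovery
#' rate adjustment with enforced monotonicity.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"fdr_bh"`.
#' @return Adjusted p-values, same length and order as `pvals`.
#' @export
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "fdr_bh") # all 0.04
adjust_pvalues <- function(pvals, method = c("bonferroni", "fdr_bh")) {
  method <- match.arg(method)
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  stats::p.adjust(pvals, method = switch(method, bonferroni = "bonferroni",
                                         fdr_bh = "BH"))
}

.col_as_name <- function(data, quo, what) {
  nm <- rlang::as_name(quo)
  if (!nm %in% names(data)) abort(sprintf("Column `%s` (%s) not found.", nm, what))
  nm
}

#' Mixed two-way ANOVA (between x within)
#'
#' Group-by-class mixed ANOVA: one between-subject factor (e.g. patients vs
#' healthy controls) and one within-subject factor (e.g. microstate class
#' A-E), requiring exactly one observation per subject and within level. The
#' between effect is tested against the subject-within-group error, the
#' within and interaction effects against the class-by-subject error, as in
#' the classical univariate mixed design (no sphericity correction). Partial
#' eta squared is `SS_effect / (SS_effect + SS_error)` of the matching error
#' stratum.
#'
#' @param data A data frame in long format.
#' @param value,subject,within,between Bare column names.
#' @return A tibble with rows for the between, within, and interaction
#'   effects: `effect`, `term`, `df1`, `df2`, `statistic` (F), `p_value`,
#'   `partial_eta_sq`.
#' @export
mixed_anova <- function(data, value, subject, within, between) {
  v <- .col_as_name(data, rlang::enquo(value), "value")
  s <- .col_as_name(data, rlang::enquo(subject), "subject")
  w <- .col_as_name(data, rlang::enquo(within), "within")
  b <- .col_as_name(data, rlang::enquo(between), "between")
  df <- data.frame(
    .value = data[[v]],
    .subject = factor(data[[s]]),
    .within = factor(data[[w]]),
    .between = factor(data[[b]])
  )
  counts <- table(df$.subject, df$.within)
  if (any(counts != 1L)) {
    abort("Design must be complete and balanced: exactly one observation per subject and within level.")
  }
  fit <- stats::aov(.value ~ .between * .within + Error(.subject),
                    data = df)
  sm <- summary(fit)
  subj_tab <- as.data.frame(sm[["Error: .subject"]][[1]])
  within_tab <- as.data.frame(sm[["Error: Within"]][[1]])
  row_of <- function(tab, name) {
    i <- which(trimws(rownames(tab)) == name)
    if (length(i) != 1L) abort(sprintf("ANOVA term `%s` not found.", name))
    tab[i, ]
  }
  subj_err <- row_of(subj_tab, "Residuals")
  within_err <- row_of(within_tab, "Residuals")
  mk <- function(effect, term, r, err) {
    ss <- r[["Sum Sq"]]
    ss_err <- err[["Sum Sq"]]
    pes <- if (ss + ss_err > 0) ss / (ss + ss_err) else NA_real_
    tibble(effect = effect, term = term, df1 = r[["Df"]], df2 = err[["Df"]],
           statistic = r[["F value"]], p_value = r[["Pr(>F)"]],
           partial_eta_sq = pes)
  }
  bind_rows(
    mk("between", b, row_of(subj_tab, ".between"), subj_err),
    mk("within", w, row_of(within_tab, ".within"), within_err),
    mk("interaction", paste0(b, ":", w), row_of(within_tab, ".between:.within"),
       within_err)
  )
}

#' Simple effects of the between factor at each within level
#'
#' Follow-up decomposition for a significant interaction: at each level of
#' the within factor, a one-way between-groups ANOVA (equivalent to an
#' independent t-test for two groups, up to `F = t^2`), with multiplicity
#' correction across levels.
#'
#' @inheritParams mixed_anova
#' @param p_adjust_method Passed to [adjust_pvalues()].
#' @return A tibble with one row per within level: `level`, `df1`, `df2`,
#'   `statistic` (F), `p_value`, `p_adjusted`.
#' @export
simple_effects <- function(data, value, subject, within, between,
                           p_adjust_method = "bonferroni") {
  v <- .col_as_name(data, rlang::enquo(value), "value")
  w <- .col_as_name(data, rlang::enquo(within), "within")
  b <- .col_as_name(data, rlang::enquo(between), "between")
  levels_w <- unique(data[[w]])
  rows <- lapply(levels_w, function(lv) {
    sub <- data[data[[w]] == lv, ]
    fit <- stats::aov(sub[[v]] ~ factor(sub[[b]]))
    tab <- summary(fit)[[1]]
    tibble(level = as.character(lv), df1 = tab[1, "Df"], df2 = tab[2, "Df"],
           statistic = tab[1, "F value"], p_value = tab[1, "Pr(>F)"])
  })
  out <- bind_rows(rows)
  out$p_adjusted <- adjust_pvalues(out$p_value, p_adjust_method)
  out
}

#' Change-score correlation matrix
#'
#' Pearson correlation of every microstate-parameter change score against
#' every EMG-feature change score across subjects, with multiplicity
#' correction over all cells. Inputs are wide subject-by-variable tables
#' sharing a subject identifier column; with the five classes and three
#' temporal parameters against ten muscles this yields the 15 x 10 layout of
#' the study's correlation tables.
#'
#' @param microstate_deltas,emg_deltas Wide tibbles: one subject column plus
#'   numeric change-score columns.
#' @param subject_col Name of the shared subject identifier column.
#' @param p_adjust_method Passed to [adjust_pvalues()].
#' @return A long tibble: `parameter`, `muscle`, `r`, `p_value`,
#'   `p_adjusted`, `sig` (stars at adjusted p < 0.05 / < 0.01).
#' @export
correlation_matrix <- function(microstate_deltas, emg_deltas,
                               subject_col = "subject",
                               p_adjust_method = "fdr_bh") {
  for (tbl in list(microstate_deltas, emg_deltas)) {
    if (!subject_col %in% names(tbl)) {
      abort(sprintf("Both tables need a `%s` column.", subject_col))
    }
  }
  if (!setequal(microstate_deltas[[subject_col]], emg_deltas[[subject_col]]) ||
      anyDuplicated(microstate_deltas[[subject_col]]) ||
      anyDuplicated(emg_deltas[[subject_col]])) {
    abort("Subject sets of the two tables differ.")
  }
  emg_deltas <- emg_deltas[match(microstate_deltas[[subject_col]],
                                 emg_deltas[[subject_col]]), ]
  params <- setdiff(names(microstate_deltas), subject_col)
  muscles <- setdiff(names(emg_deltas), subject_col)
  grid <- expand.grid(parameter = params, muscle = muscles,
                      stringsAsFactors = FALSE)
  res <- purrr::pmap(grid, function(parameter, muscle) {
    ct <- pearson_corr(microstate_deltas[[parameter]], emg_deltas[[muscle]])
    tibble(parameter = parameter, muscle = muscle, r = ct$estimate,
           p_value = ct$p_value)
  })
  out <- bind_rows(res)
  out$p_adjusted <- adjust_pvalues(out$p_value, p_adjust_method)
  out$sig <- cut(out$p_adjusted, breaks = c(-Inf, 0.01, 0.05, Inf),
                 labels = c("**", "*", ""))
  out$parameter <- factor(out$parameter, levels = params)
  out$muscle <- factor(out$muscle, levels = muscles)
  out
}

#' Clinical outcome report
#'
#' Pre/post summary of the clinical scales in the style of an outcomes table:
#' mean and SD before and after treatment, paired t statistic, degrees of
#' freedom and two-sided p per outcome.
#'
#' @param scores A table like [clinical_scores()], with paired
#'   `<outcome>_pre` / `<outcome>_post` numeric columns.
#' @param outcomes Base names of the outcome columns.
#' @return A tibble with one row per outcome.
#' @export
#' @examples
#' clinical_outcomes(clinical_scores())
clinical_outcomes <- function(scores, outcomes = c("fma_ue", "arat")) {
  rows <- lapply(outcomes, function(o) {
    pre <- scores[[paste0(o, "_pre")]]
    post <- scores[[paste0(o, "_post")]]
    if (is.null(pre) || is.null(post)) {
      abort(sprintf("Columns %s_pre / %s_post not found.", o, o))
    }
    tt <- paired_t(pre, post)
    tibble(outcome = o, pre_mean = mean(pre), pre_sd = stats::sd(pre),
           post_mean = mean(post), post_sd = stats::sd(post),
           statistic = tt$statistic, df = tt$df, p_value = tt$p_value)
  })
  bind_rows(rows)
}

#' Pre/post comparison with a normality gate
#'
#' Reports both the paired t-test and the Wilcoxon signed-rank test for a
#' pre/post pair, plus a Shapiro-Wilk check of the paired differences at
#' `alpha`; the `recommended` column marks the parametric test when the
#' differences pass the normality check and the signed-rank test otherwise.
#'
#' @param pre,post Paired numeric vectors.
#' @param alpha Normality-gate level (default 0.05).
#' @return A two-row tibble (one per test) with an added `shapiro_p` and
#'   logical `recommended`.
#' @export
compare_pre_post <- function(pre, post, alpha = 0.05) {
  d <- post - pre
  sh <- stats::shapiro.test(d)$p.value
  tt <- paired_t(pre, post)
  wt <- wilcoxon_signed_rank(pre, post)
  out <- bind_rows(tt, wt)
  out$shapiro_p <- sh
  out$recommended <- if (sh >= alpha) c(TRUE, FALSE) else c(FALSE, TRUE)
  out
}
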