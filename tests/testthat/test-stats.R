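test_that("paired t is anti-symmetric and rejects degenerate differences", {
  set.seed(1)
  x <- rnorm(15)
  y <- rnorm(15)
  a <- paired_t(x, y)
  b <- paired_t(y, x)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$df, 14)
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "[Dd]egenerate|zero variance")
  expect_error(paired_t(1:3, 1:4), "length")
})

test_that("independent t matches the hand pooled-variance formula", {
  r <- independent_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3.674, tolerance = 5e-4)
  expect_equal(r$df, 4)
  expect_equal(independent_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_error(independent_t(1, c(1, 2)), "n >= 2")
  expect_error(independent_t(c(2, 2, 2), c(3, 3, 3)), "[Dd]egenerate")
  w <- independent_t(c(1, 2, 3), c(4, 5, 60), welch = TRUE)
  expect_lt(w$df, 4)  # Welch reduces the degrees of freedom
})

test_that("signed-rank p is exact by enumeration for small n", {
  # 5 strictly positive differences: two-sided p = 2/2^5
  r <- wilcoxon_signed_rank(rep(0, 5), c(1, 2, 3, 4, 5))
  expect_equal(r$p_value, 0.0625)
  expect_equal(r$statistic, 15)
  # symmetric +/- pairs of equal magnitude sit at the null centre
  s <- wilcoxon_signed_rank(rep(0, 6), c(1, -1, 2, -2, 3, -3))
  expect_equal(s$statistic, 6 * 7 / 4)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
})

test_that("signed-rank agrees with a full 2^n sign-pattern enumeration oracle", {
  enum_oracle <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    rk <- rank(abs(d))
    v_obs <- sum(rk[d > 0])
    vs <- vapply(seq_len(2^n) - 1L, function(mask) {
      signs <- bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L
      sum(rk[signs])
    }, numeric(1))
    mu <- n * (n + 1) / 4
    min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
  }
  set.seed(42)
  for (rep in 1:4) {
    d <- round(rnorm(8), 1)  # rounding creates occasional ties
    d[d == 0] <- 0.5
    r <- wilcoxon_signed_rank(rep(0, 8), d)
    expect_equal(r$p_value, enum_oracle(d), tolerance = 1e-12)
  }
  # cross-check against the R reference on a tie-free case
  set.seed(9)
  d <- rnorm(12)
  expect_equal(wilcoxon_signed_rank(rep(0, 12), d)$p_value,
               stats::wilcox.test(d, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("exact and normal-approximation signed-rank p agree at n = 20", {
  set.seed(7)
  d <- rnorm(20, mean = 0.3)
  exact <- wilcoxon_signed_rank(rep(0, 20), d, exact_max = 25)$p_value
  approx <- wilcoxon_signed_rank(rep(0, 20), d, exact_max = 5)$p_value
  expect_lt(abs(exact - approx), 0.02)
})

test_that("Pearson correlation hits its closed forms", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_corr(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearson_corr(x, -x)$estimate, -1)
  r <- pearson_corr(x, c(2, 1, 4, 3, 5))
  expect_equal(r$estimate, 0.8)
  expect_equal(r$df, 3)
  expect_error(pearson_corr(1:2, 1:2), "n >= 3")
  expect_error(pearson_corr(x, rep(1, 5)), "variance")
})

test_that("multiplicity corrections match their definitional oracles", {
  expect_equal(adjust_pvalues(c(0.01, 0.04), "bonferroni"), c(0.02, 0.08))
  expect_equal(adjust_pvalues(c(0.8, 0.9), "bonferroni"), c(1, 1))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "fdr_bh"),
               rep(0.04, 4))
  # BH step-up definition with monotonicity on a random vector
  set.seed(11)
  p <- runif(20)
  m <- length(p)
  o <- order(p)
  stepup <- numeric(m)
  stepup[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(adjust_pvalues(p, "fdr_bh"), pmin(1, stepup))
  # adjusted values are monotone in raw p rank
  adj <- adjust_pvalues(p, "fdr_bh")
  expect_true(all(diff(adj[o]) >= -1e-12))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("mixed ANOVA matches an explicit sums-of-squares decomposition", {
  # 4 subjects (2 per group) x 2 within levels
  df <- tibble::tibble(
    subject = rep(c("s1", "s2", "s3", "s4"), each = 2),
    group = rep(c("pat", "pat", "hc", "hc"), each = 2),
    class = rep(c("A", "B"), times = 4),
    value = c(3, 5, 4, 7, 1, 2, 2, 2)
  )
  res <- mixed_anova(df, value, subject, within = class, between = group)
  # oracle: classical mixed-design SS decomposition
  y <- df$value
  gm <- mean(y)
  subj_means <- tapply(y, df$subject, mean)
  grp_means <- tapply(y, df$group, mean)
  cls_means <- tapply(y, df$class, mean)
  cell_means <- tapply(y, list(df$group, df$class), mean)
  n_w <- 2; n_per_g <- 2
  ss_between <- n_w * n_per_g * sum((grp_means - gm)^2)
  ss_subj <- n_w * sum((subj_means - gm)^2)
  ss_subj_err <- ss_subj - ss_between
  ss_within <- 4 * sum((cls_means - gm)^2)
  ss_cells <- n_per_g * sum((cell_means - gm)^2)
  ss_int <- ss_cells - ss_between - ss_within
  ss_tot <- sum((y - gm)^2)
  ss_w_err <- ss_tot - ss_subj - ss_within - ss_int
  f_between <- (ss_between / 1) / (ss_subj_err / 2)
  f_within <- (ss_within / 1) / (ss_w_err / 2)
  f_int <- (ss_int / 1) / (ss_w_err / 2)
  expect_equal(res$statistic[res$effect == "between"], f_between, tolerance = 1e-9)
  expect_equal(res$statistic[res$effect == "within"], f_within, tolerance = 1e-9)
  expect_equal(res$statistic[res$effect == "interaction"], f_int, tolerance = 1e-9)
  expect_equal(res$partial_eta_sq[res$effect == "between"],
               ss_between / (ss_between + ss_subj_err), tolerance = 1e-9)
  # SS additivity on the balanced toy
  expect_equal(ss_between + ss_subj_err + ss_within + ss_int + ss_w_err,
               ss_tot, tolerance = 1e-9)
})

test_that("mixed ANOVA edge cases: null interaction and missing cells", {
  # cell means identical across groups for every class -> interaction F = 0
  df <- tibble::tibble(
    subject = rep(paste0("s", 1:4), each = 2),
    group = rep(c("a", "a", "b", "b"), each = 2),
    class = rep(c("A", "B"), times = 4),
    # cell means: class effect +2 in both groups, subject-level wobble only
    value = c(1, 3, 3, 5, 1.5, 4.5, 2.5, 3.5)
  )
  res <- mixed_anova(df, value, subject, within = class, between = group)
  expect_equal(res$statistic[res$effect == "interaction"], 0, tolerance = 1e-9)
  expect_error(mixed_anova(df[-1, ], value, subject, within = class,
                           between = group), "balanced")
})

test_that("simple effects decompose the interaction per within level", {
  set.seed(13)
  df <- tibble::tibble(
    subject = rep(paste0("s", 1:10), each = 2),
    group = rep(rep(c("pat", "hc"), each = 2), 5),
    class = rep(c("A", "B"), times = 10),
    value = rnorm(20)
  )
  df$value[df$class == "A" & df$group == "pat"] <-
    df$value[df$class == "A" & df$group == "pat"] + 5
  se <- simple_effects(df, value, subject, within = class, between = group)
  expect_equal(nrow(se), 2)
  expect_lt(se$p_adjusted[se$level == "A"], 0.05)
  # two groups: F = t^2
  tA <- independent_t(df$value[df$class == "A" & df$group == "pat"],
                      df$value[df$class == "A" & df$group == "hc"])
  expect_equal(se$statistic[se$level == "A"], tA$statistic^2, tolerance = 1e-9)
})

test_that("change-score correlation matrices have the study layout and a sane null", {
  set.seed(17)
  n <- 20
  classes <- LETTERS[1:5]
  metrics <- c("duration", "coverage", "occurrence")
  ms <- tibble::as_tibble(
    c(list(subject = 1:n),
      stats::setNames(
        lapply(seq_len(15), function(i) rnorm(n)),
        as.vector(outer(metrics, classes, paste, sep = "_"))
      ))
  )
  emg <- tibble::as_tibble(
    c(list(subject = 1:n),
      stats::setNames(lapply(1:10, function(i) rnorm(n)), emg_muscles_10)))
  cm <- correlation_matrix(ms, emg)
  expect_equal(nrow(cm), 150)
  expect_equal(length(unique(cm$parameter)), 15)
  expect_equal(length(unique(cm$muscle)), 10)
  # independent columns: small mean |r| under the null
  expect_lte(mean(abs(cm$r)), 0.35)
  # a perfect linear relation gives |r| = 1 in that row
  emg2 <- emg
  emg2$BB <- 3 * ms$duration_A - 2
  cm2 <- correlation_matrix(ms, emg2)
  expect_equal(cm2$r[cm2$parameter == "duration_A" & cm2$muscle == "BB"], 1,
               tolerance = 1e-12)
  bad <- emg
  bad$subject[1] <- 99
  expect_error(correlation_matrix(ms, bad), "Subject sets")
})

test_that("the clinical outcome report reproduces the published scale statistics", {
  rep_tbl <- clinical_outcomes(clinical_scores())
  expect_equal(rep_tbl$pre_mean, c(31.50, 26.30))
  expect_equal(rep_tbl$post_mean, c(33.65, 27.25))
  expect_equal(round(rep_tbl$statistic, 3), c(4.357, 2.826))
  expect_equal(rep_tbl$df, c(19, 19))
  expect_true(all(rep_tbl$p_value < 0.05))
})

test_that("the normality-gated comparison reports both tests with a recommendation", {
  set.seed(23)
  pre <- rnorm(15)
  post <- pre + rnorm(15, 0.5)
  cp <- compare_pre_post(pre, post)
  expect_equal(nrow(cp), 2)
  expect_equal(sum(cp$recommended), 1)
  expect_setequal(cp$test, c("paired_t", "wilcoxon_signed_rank"))
})
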