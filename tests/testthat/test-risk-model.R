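test_that("Fisher LDA matches the closed form and orients toward the
          risk class", {
  # 1-D: class means 0 and 1 -> positive weight, ordered scores
  set.seed(1)
  x <- matrix(c(stats::rnorm(30, 0, 1), stats::rnorm(30, 1, 1)))
  y <- rep(0:1, each = 30L)
  fit <- fit_lda(x, y)
  expect_gt(fit$weights[1L], 0)
  expect_gt(mean(fit$scores[y == 1L]), mean(fit$scores[y == 0L]))

  # 2-D: weights equal solve(pooled covariance, mean difference)
  set.seed(2)
  n <- 200L
  x <- cbind(stats::rnorm(n), stats::rnorm(n))
  x[, 2L] <- 0.6 * x[, 1L] + 0.8 * x[, 2L]
  y <- rep(0:1, each = n / 2L)
  x[y == 1L, 1L] <- x[y == 1L, 1L] + 1.2
  fit <- fit_lda(x, y)
  mu0 <- colMeans(x[y == 0L, ]); mu1 <- colMeans(x[y == 1L, ])
  sp <- (crossprod(sweep(x[y == 0L, ], 2L, mu0)) +
           crossprod(sweep(x[y == 1L, ], 2L, mu1))) / (n - 2L)
  expect_equal(unname(fit$weights), drop(solve(sp, mu1 - mu0)),
               tolerance = 1e-8)
  # independent oracle: MASS::lda discriminant direction (collinear)
  ld <- MASS::lda(x, grouping = y)$scaling[, 1L]
  cosang <- abs(sum(fit$weights * ld)) /
    sqrt(sum(fit$weights^2) * sum(ld^2))
  expect_gt(cosang, 1 - 1e-8)

  # identical classes: AUC of the scores is chance
  set.seed(3)
  x0 <- matrix(stats::rnorm(200L), ncol = 2L)
  fit0 <- fit_lda(x0, rep(0:1, 50L))
  expect_lt(abs(auc_mw(fit0$scores, rep(0:1, 50L)) - 0.5), 0.15)

  # singular pooled covariance falls back to ridge with a warning
  xs <- cbind(x[, 1L], x[, 1L])
  expect_warning(fit_lda(xs, y), "ridge")
})

test_that("AUC agrees with pROC and is invariant to monotone
          transforms", {
  set.seed(4)
  s <- stats::rnorm(80)
  y <- stats::rbinom(80, 1L, stats::plogis(s))
  if (length(unique(y)) == 2L) {
    a <- auc_mw(s, y)
    expect_equal(a, as.numeric(pROC::auc(pROC::roc(y, s,
                                                   quiet = TRUE))),
                 tolerance = 1e-12)
    expect_equal(auc_mw(exp(3 * s) + 5, y), a, tolerance = 1e-12)
    expect_equal(auc_mw(rank(s), y), a, tolerance = 1e-12)
  }
  # ties counted one half
  expect_equal(auc_mw(c(1, 1, 1, 1), c(0, 0, 1, 1)), 0.5)
})

test_that("biomarker evaluation matches brute-force ROC enumeration
          and the 2x2 cross-product odds ratio", {
  # perfectly separated scores
  ev <- suppressWarnings(   # glm flags the intended perfect separation
    evaluate_biomarker(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)))
  expect_equal(ev$auc, 1.0)
  expect_gt(ev$cutoff, 3)
  expect_lte(ev$cutoff, 10)

  # stepping-score example: cutoff maximising J lies in (2, 3]
  ev2 <- suppressWarnings(
    evaluate_biomarker(c(1, 2, 3, 4), c(0, 0, 1, 1)))
  expect_equal(ev2$auc, 1.0)
  expect_gt(ev2$cutoff, 2)
  expect_lte(ev2$cutoff, 3)

  # random scores: brute-force enumeration over all thresholds
  set.seed(5)
  s <- round(stats::rnorm(60), 1)   # ties on purpose
  y <- stats::rbinom(60, 1L, 0.4)
  ev3 <- evaluate_biomarker(s, y)
  best_j <- -Inf; best_t <- NA
  for (t in sort(unique(s))) {
    sens <- sum(s >= t & y == 1L) / sum(y == 1L)
    spec <- sum(s < t & y == 0L) / sum(y == 0L)
    if (sens + spec - 1 > best_j + 1e-12) {
      best_j <- sens + spec - 1; best_t <- t
    }
  }
  expect_equal(ev3$cutoff, best_t)
  expect_equal(ev3$youden, best_j)
  # brute-force pairwise AUC
  pairs <- outer(s[y == 1L], s[y == 0L],
                 function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(ev3$auc, mean(pairs), tolerance = 1e-12)

  # binary score: per-unit OR equals the contingency cross-product
  sb <- c(rep(0, 25), rep(1, 15), rep(0, 5), rep(1, 15))
  yb <- c(rep(0, 40), rep(1, 20))
  tab <- table(sb, yb)
  cross <- (tab["1", "1"] * tab["0", "0"]) /
    (tab["0", "1"] * tab["1", "0"])
  ev4 <- evaluate_biomarker(sb, yb)
  expect_equal(ev4$or_per_unit, unname(cross), tolerance = 1e-6)
  expect_true(ev4$or_ci[1L] <= ev4$or_per_sd &&
                ev4$or_per_sd <= ev4$or_ci[2L])

  expect_error(evaluate_biomarker(c(1, 2, 3), c(1, 1, 1)), "classes")
})

test_that("feature selection recovers planted drivers, never loses to
          its best single feature, and is seed-stable", {
  ft <- simulate_feature_table(n = 400L, seed = 60L)
  pool <- ft[, setdiff(names(ft), "adverse_outcome")]
  m <- select_features(pool, ft$adverse_outcome, seed = 60L)
  expect_true(all(c("apef", "z1") %in% m$selected_features))
  expect_lte(length(m$selected_features), 3L)
  expect_gt(m$cv_auc, 0.7)

  # the search includes singletons: never below the best single
  singles <- vapply(names(pool), function(nm)
    select_features(pool[, nm, drop = FALSE], ft$adverse_outcome,
                    seed = 60L)$cv_auc, 0)
  expect_gte(m$cv_auc, max(singles))

  # pool of one feature -> that feature, trivially
  m1 <- select_features(pool[, "apef", drop = FALSE],
                        ft$adverse_outcome, seed = 60L)
  expect_identical(m1$selected_features, "apef")

  # same seed, same answer
  m2 <- select_features(pool, ft$adverse_outcome, seed = 60L)
  expect_identical(m$selected_features, m2$selected_features)
  expect_equal(m$cv_auc, m2$cv_auc)

  # stratified folds preserve class counts within 1
  y <- ft$adverse_outcome
  fold <- bivatlas:::stratified_folds(y, 4L, 60L)
  pos_per_fold <- table(fold[y == 1L])
  expect_lte(diff(range(pos_per_fold)), 1L)
})

test_that("selection over a pool of pure noise carries an optimistic
          bias, while a fixed model is unbiased under permutation", {
  # documented selection-bias property: mean selected cv AUC above
  # 0.5 when searching many null features
  set.seed(61)
  biased <- replicate(8, {
    n <- 200L
    pool <- as.data.frame(matrix(stats::rnorm(n * 6L), n))
    y <- rep(c(1L, 0L), c(30L, 170L))[sample.int(n)]
    select_features(pool, y, seed = sample.int(1e6, 1L))$cv_auc
  })
  expect_gt(mean(biased), 0.5)
  # fixed single feature, permuted labels: centred at chance
  set.seed(62)
  nulls <- replicate(12, {
    n <- 300L
    pool <- data.frame(x = stats::rnorm(n))
    y <- rep(c(1L, 0L), c(60L, 240L))[sample.int(n)]
    select_features(pool, y, seed = sample.int(1e6, 1L))$cv_auc
  })
  expect_lt(abs(mean(nulls) - 0.5), 0.06)
})

test_that("staged analysis composes pools correctly and the null
          cohort shows chance discrimination everywhere", {
  ft <- simulate_feature_table(n = 400L, seed = 63L)
  st <- staged_analysis(ft, seed = 63L)
  # stage restricted to one pool == direct call
  direct <- select_features(ft[, attr(ft, "pools")$regional,
                               drop = FALSE],
                            ft$adverse_outcome, seed = 63L)
  expect_identical(st$regional$selected_features,
                   direct$selected_features)
  expect_equal(st$regional$cv_auc, direct$cv_auc)
  # drivers found by their stages; composite at least on par with the
  # preliminary stages (small CV slack allowed)
  expect_identical(st$regional$selected_features, "apef")
  expect_identical(st$shape$selected_features, "z1")
  expect_gte(st$composite$cv_auc,
             max(st$summary$cv_auc[1:3]) - 0.02)
  expect_setequal(
    st$summary$stage,
    c("conventional", "regional", "shape", "composite"))

  # outcome independent of all features -> all stages near chance
  ft0 <- simulate_feature_table(n = 400L, beta_apef = 0,
                                beta_mode = 0, seed = 64L)
  st0 <- staged_analysis(ft0, seed = 64L)
  expect_true(all(abs(st0$summary$cv_auc - 0.5) < 0.15))
})

test_that("PRVI analysis: variance explained matches construction,
          degenerate inputs rejected", {
  # prvi = 0.7 * z_latent + noise with matched variances -> R^2 ~ 1/2
  set.seed(65)
  n <- 600L
  z <- matrix(stats::rnorm(n * 3L), n, 3L)
  colnames(z) <- paste0("z", 1:3)
  prvi <- 25 + 0.7 * z[, 2L] + stats::rnorm(n, 0, 0.7)
  apef <- stats::rnorm(n)
  y <- stats::rbinom(n, 1L, stats::plogis(-2 + 0.8 * apef))
  ft <- data.frame(adverse_outcome = y, apef = apef, rvef = rnorm(n),
                   prvi = prvi, z)
  attr(ft, "pools") <- list(conventional = "rvef", regional = "apef",
                            shape = paste0("z", 1:3))
  comp <- select_features(ft[, c("apef", "z1")], y, seed = 65L)
  pa <- prvi_analysis(ft, comp, seed = 65L)
  expect_identical(pa$mode_regression$modes[1L], "z2")
  expect_equal(pa$mode_regression$r2, 0.5, tolerance = 0.1)
  # PRVI unrelated to the outcome drivers: no material AUC gain
  expect_lt(pa$auc_with_prvi - pa$auc_without_prvi, 0.05)

  ft2 <- ft; ft2$prvi <- 3.7
  expect_error(prvi_analysis(ft2, comp), "constant")
  ft3 <- ft; ft3$prvi[-(1:5)] <- NA
  expect_error(prvi_analysis(ft3, comp), "fewer than 10")
})

test_that("group-comparison tables: Welch rows, Mood median rows and
          the hand-computed chi-square agree", {
  # identical groups -> p = 1
  xt <- data.frame(adverse_outcome = rep(0:1, each = 20L),
                   f = rep(seq_len(20L), 2L))
  tab <- group_comparison_table(xt, "f")
  expect_equal(tab$p_value, 1, tolerance = 1e-12)
  expect_identical(tab$sig, "")

  # strongly separated normals: overwhelming significance
  set.seed(66)
  xt2 <- data.frame(adverse_outcome = rep(0:1, each = 100L),
                    f = c(stats::rnorm(100), stats::rnorm(100, 2)))
  tab2 <- group_comparison_table(xt2, "f")
  expect_lt(tab2$p_value, 1e-10)
  expect_identical(tab2$sig, "*")

  # Mood's median test equals the 2x2 chi-square computed by hand
  set.seed(67)
  x <- stats::rnorm(50)
  g <- rep(0:1, 25L)
  mt <- mood_median_test(x, g)
  m <- stats::median(x)
  a <- sum(x > m & g == 1L); b <- sum(x > m & g == 0L)
  c_ <- sum(x <= m & g == 1L); d <- sum(x <= m & g == 0L)
  nn <- a + b + c_ + d
  chi <- nn * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  expect_equal(mt$statistic, chi, tolerance = 1e-12)
  expect_equal(mt$p_value,
               stats::pchisq(chi, 1L, lower.tail = FALSE),
               tolerance = 1e-12)

  # median-formatted rows use Mood's test
  tab3 <- group_comparison_table(xt2, "f", median_features = "f")
  expect_identical(tab3$test, "mood_median")
  expect_match(tab3$all, "\\(")

  # group of size 1: Welch undefined, reported NA
  xt4 <- data.frame(adverse_outcome = c(1L, rep(0L, 10L)),
                    f = stats::rnorm(11))
  expect_true(is.na(group_comparison_table(xt4, "f")$p_value))
})
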