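# Staged linear-discriminant risk modelling: Fisher two-class LDA,
# exhaustive feature-subset selection (up to 3 predictors) scored by
# stratified cross-validated AUC, biomarker evaluation (Mann-Whitney
# AUC, Youden cut-off, odds ratio per SD of the score), the staged
# conventional/regional/shape-mode analyses with a composite model,
# the PRVI surrogate analysis, and group-comparison tables (Welch and
# Mood's median tests).

#' Fisher two-class linear discriminant
#'
#' Weight vector proportional to \code{solve(pooled_cov, mu1 - mu0)},
#' intercept centring the score at the pooled-mean midpoint, so that
#' positive scores lean toward class 1 (the higher-risk class). A
#' singular pooled covariance is ridge-regularized with
#' \code{lambda = 1e-6 * trace / d} and a warning.
#'
#' @param x numeric matrix (subjects x features), ideally
#'   standardized.
#' @param y binary labels (0/1), each class with >= 2 members.
#' @return list: \code{weights}, \code{intercept}, \code{scores}.
#' @export
fit_lda <- function(x, y) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) != 2L || min(table(y)) < 2L)
    stop("need two classes with at least 2 members each")
  x0 <- x[y == 0L, , drop = FALSE]
  x1 <- x[y == 1L, , drop = FALSE]
  mu0 <- colMeans(x0)
  mu1 <- colMeans(x1)
  n0 <- nrow(x0); n1 <- nrow(x1)
  sp <- (crossprod(sweep(x0, 2L, mu0)) + crossprod(sweep(x1, 2L, mu1))) /
    (n0 + n1 - 2L)
  w <- tryCatch(solve(sp, mu1 - mu0), error = function(e) {
    warning("singular pooled covariance; ridge-regularized inverse")
    lam <- 1e-6 * sum(diag(sp)) / ncol(x)
    solve(sp + diag(lam, ncol(x)), mu1 - mu0)
  })
  b <- -sum(w * (mu0 + mu1) / 2)
  scores <- drop(x %*% w) + b
  list(weights = stats::setNames(drop(w), colnames(x)), intercept = b,
       scores = scores)
}

#' Mann-Whitney AUC of a score against binary labels
#'
#' Rank formulation with ties counted one half; equals the
#' probability that a random positive outscores a random negative.
#'
#' @param scores numeric vector.
#' @param labels binary 0/1.
#' @return AUC in [0, 1].
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment: per class, shuffled round-robin, so
# class counts per fold differ by at most 1
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# mean test-fold AUC of an LDA over stratified k-fold CV
cv_auc <- function(x, y, folds = 4L, seed = 1L) {
  fold <- stratified_folds(y, folds, seed)
  aucs <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    fit <- fit_lda(x[tr, , drop = FALSE], y[tr])
    te_scores <- drop(x[!tr, , drop = FALSE] %*% fit$weights) +
      fit$intercept
    auc_mw(te_scores, y[!tr])
  }, 0)
  mean(aucs)
}

#' Exhaustive AUC-guided feature-subset selection for LDA
#'
#' Scores every feature subset of size 1..\code{max_k} by mean AUC
#' over stratified \code{folds}-fold cross-validation (folds fixed by
#' \code{seed}) and refits the winning LDA on the full data. Ties go
#' to the smaller subset, then to lexicographic feature order. With
#' fewer positives than folds, the fold count is reduced with a
#' warning.
#'
#' @param pool data.frame or matrix of candidate features
#'   (standardized internally).
#' @param labels binary outcome per row.
#' @param max_k maximum subset size (default 3).
#' @param folds CV folds (default 4).
#' @param seed fold-assignment seed.
#' @return object of class \code{risk_model}: selected features, LDA
#'   weights, cross-validated and full-data AUC, Youden cut-off, odds
#'   ratio per score SD with 95 per cent Wald CI, per-subject scores.
#' @export
select_features <- function(pool, labels, max_k = 3L, folds = 4L,
                            seed = 1L) {
  x <- scale(as.matrix(pool))
  y <- as.integer(labels)
  cc <- stats::complete.cases(x) & !is.na(y)
  x <- x[cc, , drop = FALSE]
  y <- y[cc]
  if (sum(y == 1L) < 3L)
    stop("need at least 3 positive outcomes for cross-validated ",
         "selection")
  if (sum(y == 1L) < folds) {
    folds <- max(2L, sum(y == 1L))
    warning("fewer positives than folds; reduced to ", folds, " folds")
  }
  nm <- colnames(x)
  best <- list(auc = -Inf, feats = character())
  for (k in seq_len(min(max_k, length(nm)))) {
    for (sub in utils::combn(sort(nm), k, simplify = FALSE)) {
      a <- cv_auc(x[, sub, drop = FALSE], y, folds, seed)
      better <- a > best$auc + 1e-12 ||
        (abs(a - best$auc) <= 1e-12 &&
           (length(sub) < length(best$feats) ||
              (length(sub) == length(best$feats) &&
                 paste(sub, collapse = ",") <
                 paste(best$feats, collapse = ","))))
      if (better) best <- list(auc = a, feats = sub)
    }
  }
  fit <- fit_lda(x[, best$feats, drop = FALSE], y)
  ev <- evaluate_biomarker(fit$scores, y)
  structure(list(selected_features = best$feats,
                 lda_weights = fit$weights,
                 intercept = fit$intercept,
                 cv_auc = best$auc, full_auc = ev$auc,
                 cutoff = ev$cutoff, or_per_sd = ev$or_per_sd,
                 or_ci = ev$or_ci, folds = folds, seed = seed,
                 scores = fit$scores, labels = y,
                 subset_ids = which(cc)),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("risk_model:", paste(x$selected_features, collapse = " + "), "\n")
  cat(sprintf("  cv AUC = %.3f (stratified %d-fold), full AUC = %.3f\n",
              x$cv_auc, x$folds, x$full_auc))
  cat(sprintf("  Youden cut-off = %.3f; OR per SD = %.2f [%.2f-%.2f]\n",
              x$cutoff, x$or_per_sd, x$or_ci[1L], x$or_ci[2L]))
  invisible(x)
}

#' Evaluate a continuous score as a binary biomarker
#'
#' AUC by the Mann-Whitney formulation; the cut-off maximises
#' Youden's J (sensitivity + specificity - 1) over the observed score
#' values with "predicted positive" meaning score >= threshold, ties
#' resolved toward the lower threshold; the odds ratio comes from a
#' univariable logistic fit, reported both per 1 SD of the score and
#' per raw unit (the latter equals the 2x2 cross-product ratio for a
#' binary score), with Wald 95 per cent intervals.
#'
#' @param scores numeric vector (finite).
#' @param labels binary 0/1, both classes present.
#' @return list: \code{auc}, \code{cutoff}, \code{youden},
#'   \code{or_per_sd}, \code{or_ci}, \code{or_per_unit},
#'   \code{or_unit_ci}.
#' @export
evaluate_biomarker <- function(scores, labels) {
  y <- as.integer(labels)
  if (length(unique(y)) != 2L) stop("both classes must be present")
  if (!all(is.finite(scores))) stop("scores must be finite")
  auc <- auc_mw(scores, y)
  thr <- sort(unique(scores))
  j <- vapply(thr, function(t) {
    pred <- scores >= t
    sens <- sum(pred & y == 1L) / sum(y == 1L)
    spec <- sum(!pred & y == 0L) / sum(y == 0L)
    sens + spec - 1
  }, 0)
  best <- which(j >= max(j) - 1e-12)[1L]   # ties -> lower threshold
  glm_sd <- stats::glm(y ~ I(scores / stats::sd(scores)),
                       family = stats::binomial())
  glm_unit <- stats::glm(y ~ scores, family = stats::binomial())
  ci <- function(g) {
    co <- summary(g)$coefficients
    exp(co[2L, 1L] + c(-1, 1) * 1.96 * co[2L, 2L])
  }
  list(auc = auc, cutoff = thr[best], youden = j[best],
       or_per_sd = exp(stats::coef(glm_sd)[[2L]]), or_ci = ci(glm_sd),
       or_per_unit = exp(stats::coef(glm_unit)[[2L]]),
       or_unit_ci = ci(glm_unit))
}

#' Staged LDA analysis over feature pools
#'
#' Runs AUC-guided selection separately on (i) the conventional pool
#' (global volumes/EF/mass indexed, QRS, blood pressure), (ii) the
#' regional RV parcellation pool and (iii) the shape-mode pool, then
#' fits the composite model on the union of the three winning feature
#' sets. Pools come from \code{attr(feature_table, "pools")}.
#'
#' @param feature_table data.frame from \code{build_feature_table}.
#' @param max_k,folds,seed forwarded to \code{select_features}.
#' @return list of class \code{staged_analysis} with elements
#'   \code{conventional}, \code{regional}, \code{shape},
#'   \code{composite} (risk_model each) and a \code{summary}
#'   data.frame of the AUC ladder.
#' @export
staged_analysis <- function(feature_table, max_k = 3L, folds = 4L,
                            seed = 1L) {
  pools <- attr(feature_table, "pools")
  if (is.null(pools)) stop("feature_table lacks a 'pools' attribute")
  y <- feature_table$adverse_outcome
  run <- function(feats) select_features(feature_table[, feats,
                                                       drop = FALSE],
                                         y, max_k, folds, seed)
  st <- list(conventional = run(pools$conventional),
             regional = run(pools$regional),
             shape = run(pools$shape))
  winners <- unique(unlist(lapply(st, `[[`, "selected_features")))
  st$composite <- run(winners)
  st$summary <- data.frame(
    stage = c("conventional", "regional", "shape", "composite"),
    features = vapply(st[1:4], function(m)
      paste(m$selected_features, collapse = "+"), ""),
    cv_auc = vapply(st[1:4], `[[`, 0, "cv_auc"),
    full_auc = vapply(st[1:4], `[[`, 0, "full_auc"),
    row.names = NULL)
  class(st) <- "staged_analysis"
  st
}

#' @export
print.staged_analysis <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' PRVI surrogate analysis
#'
#' On subjects with non-missing pulmonary regurgitant volume index:
#' (a) adds PRVI to the composite predictors and compares
#' cross-validated AUC with and without it; (b) univariable linear
#' regressions of PRVI on the composite risk score, RVEF and RV
#' apical EF (R^2 and p); (c) forward-selected linear regression of
#' PRVI on shape-mode z-scores (at most \code{max_modes} modes,
#' partial-F entry at p < 0.05); (d) optionally synthesizes +/- 2 SD
#' shapes along the PRVI regression direction and along a supplied
#' outcome-risk direction for pattern comparison.
#'
#' @param feature_table data.frame with \code{prvi} column and pools.
#' @param composite risk_model from \code{staged_analysis}.
#' @param atlas optional shape_atlas for step (d).
#' @param risk_direction optional z-space direction of the outcome
#'   model (defaults to the shape-pool LDA weights embedded in zeros).
#' @param max_modes cap on modes entering step (c).
#' @param folds,seed CV controls for step (a).
#' @return list of class \code{prvi_analysis}.
#' @export
prvi_analysis <- function(feature_table, composite, atlas = NULL,
                          risk_direction = NULL, max_modes = 3L,
                          folds = 4L, seed = 1L) {
  if (!"prvi" %in% names(feature_table)) stop("no prvi column")
  pools <- attr(feature_table, "pools")
  has <- !is.na(feature_table$prvi)
  if (sum(has) < 10L) stop("fewer than 10 subjects with PRVI")
  ft <- feature_table[has, , drop = FALSE]
  if (stats::sd(ft$prvi) == 0) stop("PRVI constant; regression undefined")
  y <- ft$adverse_outcome

  # (a) discriminative added value
  base_feats <- composite$selected_features
  x_base <- scale(as.matrix(ft[, base_feats, drop = FALSE]))
  x_plus <- cbind(x_base, prvi = drop(scale(ft$prvi)))
  f_use <- min(folds, sum(y == 1L))
  auc_without <- cv_auc(x_base, y, f_use, seed)
  auc_with <- cv_auc(x_plus, y, f_use, seed)
  auc_prvi_alone <- cv_auc(x_plus[, "prvi", drop = FALSE], y, f_use, seed)

  # (b) univariable regressions of PRVI on key predictors
  risk_score <- drop(x_base %*% composite$lda_weights)
  uni <- function(x) {
    fit <- stats::lm(ft$prvi ~ x)
    s <- summary(fit)
    c(r2 = s$r.squared, p = stats::coef(s)[2L, 4L])
  }
  uni_tab <- rbind(risk_score = uni(risk_score),
                   rvef = if ("rvef" %in% names(ft)) uni(ft$rvef),
                   apef = if ("apef" %in% names(ft)) uni(ft$apef))

  # (c) forward selection of shape modes explaining PRVI
  zs <- as.matrix(ft[, pools$shape, drop = FALSE])
  chosen <- character()
  fit0 <- stats::lm(ft$prvi ~ 1)
  repeat {
    if (length(chosen) >= max_modes) break
    cand <- setdiff(colnames(zs), chosen)
    if (!length(cand)) break
    pvals <- vapply(cand, function(cn) {
      fit1 <- stats::lm(ft$prvi ~ zs[, c(chosen, cn)])
      stats::anova(fit0, fit1)[2L, "Pr(>F)"]
    }, 0)
    if (min(pvals) > 0.05) break
    pick <- names(which.min(pvals))
    chosen <- c(chosen, pick)
    fit0 <- stats::lm(ft$prvi ~ zs[, chosen])
  }
  mode_fit <- if (length(chosen)) {
    s <- summary(fit0)
    list(modes = chosen,
         coefficients = stats::setNames(stats::coef(fit0)[-1L], chosen),
         r2 = s$r.squared)
  } else list(modes = character(), coefficients = numeric(), r2 = 0)

  # (d) +/- 2 SD shape synthesis for pattern comparison
  shapes <- NULL
  if (!is.null(atlas) && length(mode_fit$modes)) {
    dir_prvi <- rep(0, atlas$n_retained)
    ki <- match(mode_fit$modes, paste0("z", seq_len(atlas$n_retained)))
    dir_prvi[ki] <- mode_fit$coefficients
    if (is.null(risk_direction)) risk_direction <- dir_prvi
    shapes <- list(
      prvi_plus2 = synthesize_shape(atlas, dir_prvi, 2),
      prvi_minus2 = synthesize_shape(atlas, dir_prvi, -2),
      risk_plus2 = synthesize_shape(atlas, risk_direction, 2),
      risk_minus2 = synthesize_shape(atlas, risk_direction, -2))
  }
  structure(list(n_prvi = sum(has),
                 auc_without_prvi = auc_without,
                 auc_with_prvi = auc_with,
                 auc_prvi_alone = auc_prvi_alone,
                 univariable = uni_tab, mode_regression = mode_fit,
                 shapes = shapes),
            class = "prvi_analysis")
}

#' Mood's median test for a two-group comparison
#'
#' Dichotomises values at the grand median (values above vs not
#' above) and applies the Pearson chi-square test without continuity
#' correction to the resulting 2x2 table.
#'
#' @param x numeric values.
#' @param g two-level grouping.
#' @return list: \code{statistic}, \code{p_value}, \code{table}.
#' @export
mood_median_test <- function(x, g) {
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- factor(g[keep])
  m <- stats::median(x)
  tab <- table(above = x > m, group = g)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(list(statistic = NA_real_, p_value = NA_real_, table = tab))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       table = tab)
}

#' Group-comparison table (adverse vs no adverse outcome)
#'
#' For each feature: mean +/- SD per group with Welch's two-sample
#' t-test p-value, or median (IQR) with Mood's median test for
#' features flagged non-normal. Stars mark p <= 0.05. No
#' multiple-testing correction is applied.
#'
#' @param feature_table data.frame with \code{adverse_outcome}.
#' @param features columns to compare (default: all numeric except
#'   the outcome).
#' @param median_features subset reported as median (IQR) and tested
#'   by Mood's median test.
#' @return data.frame, one row per feature.
#' @export
group_comparison_table <- function(feature_table, features = NULL,
                                   median_features = character()) {
  y <- feature_table$adverse_outcome
  if (is.null(features))
    features <- setdiff(names(feature_table)[vapply(feature_table,
                                                    is.numeric, TRUE)],
                        "adverse_outcome")
  rows <- lapply(features, function(fn) {
    x <- feature_table[[fn]]
    x1 <- x[y == 1L & !is.na(x)]
    x0 <- x[y == 0L & !is.na(x)]
    if (fn %in% median_features) {
      fmt <- function(v) sprintf("%.2f (%.2f)", stats::median(v),
                                 stats::IQR(v))
      p <- mood_median_test(x, y)$p_value
      test <- "mood_median"
    } else {
      fmt <- function(v) sprintf("%.2f ± %.2f", mean(v),
                                 stats::sd(v))
      p <- if (length(x1) > 1L && length(x0) > 1L)
        stats::t.test(x1, x0, var.equal = FALSE)$p.value
      else NA_real_
      test <- "welch"
    }
    data.frame(feature = fn, all = fmt(c(x1, x0)),
               adverse = fmt(x1), no_adverse = fmt(x0),
               test = test, p_value = p,
               sig = if (!is.na(p) && p <= 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
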