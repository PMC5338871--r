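# Two-stage forward-stepwise AIC model build with correlation screening,
# 10-fold cross-validated ROC evaluation with threshold optimization and
# utility grading, and the permutation test for spurious terrain covariates.

#' Species modelability filter
#'
#' A species can be modeled when more than `min_spawners` spawning-condition
#' females were sampled (strict inequality: 90 spawners is excluded, 91
#' included). Also reports Valid Sets: gear deployments with at least
#' `min_fish_per_set` histologically sampled fish of the species.
#'
#' @param records collections data.frame.
#' @param min_spawners spawning-female threshold (default 90).
#' @param min_fish_per_set Valid Set threshold (default 3).
#' @return data.frame per species: `n_females`, `n_spawning`, `valid_sets`,
#'   `modelable`.
#' @export
filter_modelable <- function(records, min_spawners = 90, min_fish_per_set = 3) {
  sp <- sort(unique(records$species))
  out <- lapply(sp, function(s) {
    r <- records[records$species == s, , drop = FALSE]
    sets <- table(r$set_id)
    data.frame(species = s,
               n_females = nrow(r),
               n_spawning = sum(r$spawning == 1),
               valid_sets = sum(sets >= min_fish_per_set),
               modelable = sum(r$spawning == 1) > min_spawners)
  })
  do.call(rbind, out)
}

# Cramer's V between two factors (bias-uncorrected).
cramers_v <- function(a, b) {
  tab <- table(a, b)
  if (min(dim(tab)) < 2) return(NA_real_)
  n <- sum(tab)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  sqrt(as.numeric(chi2) / (n * (min(dim(tab)) - 1)))
}

#' Pairwise correlation screen for candidate terms
#'
#' Computes the pairwise association matrix between candidate terms and
#' blocks pairs with association strictly greater than `threshold` from
#' entering the same model. Terms with underlying continuous values (depth,
#' latitude, temperature, lunar, terrain statistics; the design's `raw_*`
#' columns) are compared by absolute Pearson correlation; pairs involving a
#' purely categorical term use Cramer's V, with continuous members quartile-
#' binned for the cross-tabulation. Zero-variance terms are excluded with a
#' warning.
#'
#' @param design a `spawn_design`.
#' @param terms candidate term names (default: all design terms).
#' @param threshold blocking threshold (default 0.60; strictly greater
#'   blocks, so exactly 0.60 is allowed).
#' @return list with `matrix` (associations), `blocked` (data.frame of term
#'   pairs), `threshold`.
#' @export
correlation_screen <- function(design, terms = design$terms, threshold = 0.60) {
  data <- design$data
  num_of <- function(t) {
    raw <- data[[paste0("raw_", t)]]
    if (!is.null(raw)) return(raw)
    if (t %in% names(data) && is.numeric(data[[t]])) return(data[[t]])
    NULL
  }
  fac_of <- function(t) {
    v <- data[[t]]
    if (is.factor(v)) return(v)
    bin_quantile(v, 4)
  }
  drop <- vapply(terms, function(t) {
    v <- num_of(t)
    (!is.null(v) && stats::sd(v, na.rm = TRUE) == 0) ||
      (is.null(v) && nlevels(droplevels(fac_of(t))) < 2)
  }, logical(1))
  if (any(drop)) {
    warnf("zero-variance term(s) excluded from screen: %s",
          paste(terms[drop], collapse = ", "))
    terms <- terms[!drop]
  }
  k <- length(terms)
  R <- matrix(NA_real_, k, k, dimnames = list(terms, terms))
  diag(R) <- 1
  if (k >= 2) {
    for (a in seq_len(k - 1)) for (b in seq(a + 1, k)) {
      xa <- num_of(terms[a]); xb <- num_of(terms[b])
      r <- if (!is.null(xa) && !is.null(xb)) {
        abs(stats::cor(xa, xb, use = "complete.obs"))
      } else {
        cramers_v(fac_of(terms[a]), fac_of(terms[b]))
      }
      R[a, b] <- R[b, a] <- r
    }
  }
  # strictly greater than the threshold blocks; the epsilon keeps an
  # association of exactly 0.60 on the allowed side of the boundary despite
  # floating-point roundoff
  blocked <- which(R > threshold + 1e-9 & upper.tri(R), arr.ind = TRUE)
  structure(list(
    matrix = R,
    blocked = data.frame(term1 = terms[blocked[, 1]], term2 = terms[blocked[, 2]],
                         r = R[blocked]),
    threshold = threshold
  ), class = "correlation_screen")
}

screen_blocks <- function(screen, current, candidate) {
  if (is.null(screen) || nrow(screen$blocked) == 0) return(FALSE)
  b <- screen$blocked
  # an interaction is definitionally collinear with its own margins;
  # hierarchy, not the correlation screen, governs those pairs
  margin_pair <- function(t1, t2) {
    (t1 %in% names(INTERACTION_MARGINS) && t2 %in% INTERACTION_MARGINS[[t1]]) ||
      (t2 %in% names(INTERACTION_MARGINS) && t1 %in% INTERACTION_MARGINS[[t2]])
  }
  hit <- (b$term1 == candidate & b$term2 %in% current) |
    (b$term2 == candidate & b$term1 %in% current)
  any(hit & !mapply(margin_pair, b$term1, b$term2))
}

#' Forward-stepwise AIC model build
#'
#' Starting from `base` terms, repeatedly adds the candidate term giving the
#' largest AIC decrease, skipping candidates blocked by the correlation
#' screen and interactions whose margins are not yet in the model, and stops
#' when no candidate lowers AIC. Exact AIC ties are broken by candidate
#' order. All visited models are returned ranked by AIC (the subset of
#' potential models).
#'
#' Stage 2 adds terrain (bathymetric) candidates to the fixed stage-1 winner
#' and retains a term only if it lowers AIC *and* predictive utility does
#' not degrade: its cross-validated pooled AUC must not fall more than
#' `cv_tol` points below the stage-1 model's.
#'
#' @param design a `spawn_design`.
#' @param candidates candidate term names, in preference (tie-break) order.
#' @param base terms always in the model (default none).
#' @param stage 1 (AIC only) or 2 (AIC + cross-validated utility).
#' @param screen optional [correlation_screen()] result.
#' @param k,seed cross-validation folds and seed (stage 2).
#' @param cv_tol allowed AUC drop in percentage points (stage 2, default 0.5).
#' @param reference_auc stage-1 pooled AUC (%); computed if missing (stage 2).
#' @param random,nAGQ passed to [spawn_glmm()].
#' @param hierarchy_override allow interactions without their margins.
#' @return object of class `stepwise_path`: list with `best_terms`,
#'   `best_fit`, `path` (step log), `models` (visited models ranked by AIC),
#'   `stage`, `reference_auc`.
#' @export
forward_stepwise <- function(design, candidates, base = character(0), stage = 1,
                             screen = NULL, k = 10, seed = 1, cv_tol = 0.5,
                             reference_auc = NULL, random = TRUE, nAGQ = 1,
                             hierarchy_override = FALSE) {
  fit_terms <- function(terms) {
    spawn_glmm(design, terms = terms, random = random, nAGQ = nAGQ,
               hierarchy_override = hierarchy_override, compute_sd_se = FALSE)
  }
  cur <- base
  cur_fit <- fit_terms(cur)
  if (!cur_fit$converged) stopf("base model did not converge")
  if (stage == 2 && is.null(reference_auc)) {
    reference_auc <- crossvalidate(design, terms = base, k = k, seed = seed,
                                   random = random, nAGQ = nAGQ)$auc
  }
  visited <- list(list(terms = cur, aic = cur_fit$aic))
  path <- data.frame(step = 0, added = "(base)", aic = cur_fit$aic,
                     cv_auc = NA_real_, stringsAsFactors = FALSE)
  step <- 0
  excluded <- character(0)  # stage-2 candidates that failed the utility check
  repeat {
    remaining <- setdiff(candidates, c(cur, excluded))
    if (!length(remaining)) break
    aics <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (ci in seq_along(remaining)) {
      cand <- remaining[ci]
      if (screen_blocks(screen, cur, cand)) next
      mm <- INTERACTION_MARGINS[[cand]]
      if (!is.null(mm) && !hierarchy_override &&
          !all(setdiff(mm, "temperature") %in% cur)) next
      f <- tryCatch(fit_terms(c(cur, cand)), error = function(e) NULL)
      if (is.null(f)) next
      aics[ci] <- f$aic
      fits[[ci]] <- f
      visited[[length(visited) + 1]] <- list(terms = c(cur, cand), aic = f$aic)
    }
    if (all(is.na(aics))) break
    best <- which.min(aics)  # first index wins exact ties (candidate order)
    if (!(aics[best] < cur_fit$aic)) break
    cand <- remaining[best]
    cv_auc <- NA_real_
    if (stage == 2) {
      cv_auc <- crossvalidate(design, terms = c(cur, cand), k = k, seed = seed,
                              random = random, nAGQ = nAGQ)$auc
      if (cv_auc < reference_auc - cv_tol) {
        # AIC improved but predictive utility degraded: not retained; try others
        excluded <- c(excluded, cand)
        next
      }
    }
    step <- step + 1
    cur <- c(cur, cand)
    cur_fit <- fits[[best]]
    path <- rbind(path, data.frame(step = step, added = cand,
                                   aic = cur_fit$aic, cv_auc = cv_auc))
  }
  models <- data.frame(
    terms = vapply(visited, function(v) paste(v$terms, collapse = " + "), ""),
    aic = vapply(visited, function(v) v$aic, 0)
  )
  models <- models[!duplicated(models$terms), , drop = FALSE]
  models <- models[order(models$aic), , drop = FALSE]
  structure(list(best_terms = cur, best_fit = cur_fit, path = path,
                 models = models, stage = stage, reference_auc = reference_auc),
            class = "stepwise_path")
}

#' @export
print.stepwise_path <- function(x, ...) {
  cat(sprintf("<stepwise_path> stage %d, %d step(s)\n", x$stage, max(x$path$step)))
  cat("  best model:", if (length(x$best_terms)) paste(x$best_terms, collapse = " + ")
      else "(intercept only)", sprintf(" (AIC %.2f)\n", x$best_fit$aic))
  invisible(x)
}

# AUC by the rank-sum (Mann-Whitney) formulation with midranks for ties.
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Threshold maximizing TPR + TNR under classification "score >= t"; the
# lowest optimal candidate threshold (candidates = observed scores) wins ties.
roc_threshold <- function(scores, labels) {
  cand <- sort(unique(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  # sort descending; classify >= t: cumulative positives/negatives above t
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # for each candidate t: TP = # positives with score >= t
  idx <- length(s) - findInterval(cand - 1e-12, rev(s))  # count of s >= t
  cp <- cumsum(y); cn <- cumsum(1 - y)
  tp <- ifelse(idx >= 1, cp[pmax(idx, 1)], 0) * (idx >= 1)
  fp <- ifelse(idx >= 1, cn[pmax(idx, 1)], 0) * (idx >= 1)
  tpr <- tp / n1
  tnr <- (n0 - fp) / n0
  j <- tpr + tnr
  best <- max(j)
  min(cand[j >= best - 1e-12])
}

#' K-fold cross-validated ROC evaluation
#'
#' Splits the rows into `k` class-stratified folds; per fold, fits the model
#' on the training rows, picks the classification threshold maximizing
#' TPR + TNR on the *training* ROC (lowest optimal threshold on ties), and
#' classifies the held-out test rows at that threshold. Reports the pooled
#' AUC over the concatenated test predictions (rank-sum formulation with
#' midranks), per-fold AUCs, the false positive rate `100*FP/(FP+TN)` and
#' false negative rate `100*FN/(FN+TP)` from the accumulated confusion
#' counts, the pooled threshold, and the predictive-utility grade.
#'
#' @param design a `spawn_design`.
#' @param terms model terms.
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed (recorded in the report).
#' @param random,nAGQ passed to [spawn_glmm()].
#' @return object of class `cv_report`: `auc`, `auc_by_fold`, `fpr`, `fnr`
#'   (percent), `thresholds`, `pooled_threshold`, `grade`, `folds`, `seed`.
#' @export
crossvalidate <- function(design, terms, k = 10, seed = 1, random = TRUE,
                          nAGQ = 1) {
  data <- design$data
  y <- data[[design$response %||% "spawning"]]
  n <- length(y)
  folds <- integer(n)
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  pooled_scores <- numeric(0); pooled_y <- integer(0)
  thresholds <- rep(NA_real_, k)
  auc_fold <- rep(NA_real_, k)
  TP <- FP <- TN <- FN <- 0
  for (f in seq_len(k)) {
    train <- design_subset(design, folds != f)
    test_rows <- data[folds == f, , drop = FALSE]
    fit <- spawn_glmm(train, terms = terms, random = random, nAGQ = nAGQ,
                      compute_sd_se = FALSE)
    p_train <- suppressWarnings(predict(fit, se.fit = FALSE)$fit)
    thr <- roc_threshold(p_train, train$data[[design$response %||% "spawning"]])
    thresholds[f] <- thr
    p_test <- suppressWarnings(predict(fit, newdata = test_rows, se.fit = FALSE)$fit)
    y_test <- y[folds == f]
    cls <- as.integer(p_test >= thr)
    TP <- TP + sum(cls == 1 & y_test == 1)
    FP <- FP + sum(cls == 1 & y_test == 0)
    TN <- TN + sum(cls == 0 & y_test == 0)
    FN <- FN + sum(cls == 0 & y_test == 1)
    pooled_scores <- c(pooled_scores, p_test)
    pooled_y <- c(pooled_y, y_test)
    auc_fold[f] <- 100 * auc_rank(p_test, y_test)
  }
  auc <- 100 * auc_rank(pooled_scores, pooled_y)
  structure(list(
    auc = auc,
    auc_by_fold = auc_fold,
    auc_fold_mean = mean(auc_fold, na.rm = TRUE),
    fpr = 100 * FP / (FP + TN),
    fnr = 100 * FN / (FN + TP),
    thresholds = thresholds,
    pooled_threshold = roc_threshold(pooled_scores, pooled_y),
    grade = grade_auc(auc),
    confusion = c(TP = TP, FP = FP, TN = TN, FN = FN),
    folds = folds,
    seed = seed,
    terms = terms
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> pooled AUC %.2f%% (%s), FPR %.2f%%, FNR %.2f%%\n",
              x$auc, x$grade, x$fpr, x$fnr))
  cat(sprintf("  fold-mean AUC %.2f%%, pooled threshold %.4f, seed %d\n",
              x$auc_fold_mean, x$pooled_threshold, x$seed))
  invisible(x)
}

#' Predictive-utility grade from AUC
#'
#' Maps AUC (percent) to the conventional utility grades: excellent
#' (90-100), good (80-89), fair (70-79), poor (below 70). Boundaries belong
#' to the higher grade.
#'
#' @param auc_percent AUC in percent, in `[0, 100]`.
#' @return character vector of grades.
#' @export
grade_auc <- function(auc_percent) {
  if (any(is.na(auc_percent)) || any(auc_percent < 0 | auc_percent > 100)) {
    stopf("AUC must be within [0, 100] percent")
  }
  ifelse(auc_percent >= 90, "excellent",
         ifelse(auc_percent >= 80, "good",
                ifelse(auc_percent >= 70, "fair", "poor")))
}

#' Randomization test for a spurious terrain covariate
#'
#' Assesses whether the terrain (bathymetric) term retained in the final
#' model could be spurious, given the large candidate suite. Each replicate:
#' (1) keeps all non-terrain terms at their original values and permutes
#' each terrain candidate independently across rows (preserving its marginal
#' distribution exactly), (2) refits the base model with each permuted
#' candidate singly, (3) takes the candidate with the largest AIC reduction,
#' and (4) records its percent deviance explained. The spurious probability
#' is the fraction of replicates whose best permuted candidate explains more
#' deviance than the true term does.
#'
#' @param design a `spawn_design` whose data contain the candidate columns.
#' @param base_terms the final model's non-terrain terms.
#' @param candidates terrain candidate term names.
#' @param true_term the terrain term retained in the final model.
#' @param reps replicates (default 500).
#' @param seed RNG seed.
#' @param random,nAGQ passed to [spawn_glmm()].
#' @return object of class `randomization_report`: `spurious_probability`,
#'   `true_pct_deviance`, `replicate_pct_deviance`, `reps`.
#' @export
randomization_test <- function(design, base_terms, candidates, true_term,
                               reps = 500, seed = 1, random = TRUE, nAGQ = 1) {
  if (reps < 1) stopf("reps must be >= 1")
  if (!true_term %in% names(design$data)) stopf("unknown true_term '%s'", true_term)
  base_fit <- spawn_glmm(design, terms = base_terms, random = random,
                         nAGQ = nAGQ, compute_sd_se = FALSE)
  true_fit <- spawn_glmm(design, terms = c(base_terms, true_term),
                         random = random, nAGQ = nAGQ, compute_sd_se = FALSE)
  null_dev <- base_fit$null_deviance
  true_pdev <- 100 * (base_fit$deviance - true_fit$deviance) / null_dev
  n <- base_fit$n
  use_fast <- base_fit$engine == "glm"
  y <- design$data[[design$response %||% "spawning"]]

  if (use_fast) {
    X0 <- fit_model_matrix(base_fit, design$data)
    Xc <- lapply(candidates, function(ct) {
      v <- design$data[[ct]]
      if (is.factor(v)) {
        stats::model.matrix(~v)[, -1, drop = FALSE]
      } else {
        matrix(v, ncol = 1)
      }
    })
    dev_of <- function(Xfull) {
      f <- suppressWarnings(stats::glm.fit(Xfull, y, family = stats::binomial()))
      c(dev = f$deviance + 0, aic = f$aic)
    }
  }
  fit_perm <- function(ct, perm) {
    d2 <- design
    d2$data[[ct]] <- design$data[[ct]][perm]
    f <- spawn_glmm(d2, terms = c(base_terms, ct), random = random,
                    nAGQ = nAGQ, compute_sd_se = FALSE)
    c(dev = f$deviance, aic = f$aic)
  }

  best_pdev <- rep(NA_real_, reps)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      best_red <- -Inf; best_dev <- NA_real_
      for (ci in seq_along(candidates)) {
        perm <- sample.int(n)
        if (use_fast) {
          res <- dev_of(cbind(X0, Xc[[ci]][perm, , drop = FALSE]))
        } else {
          res <- fit_perm(candidates[ci], perm)
        }
        red <- base_fit$aic - res["aic"]
        if (red > best_red) {
          best_red <- red
          best_dev <- res["dev"]
        }
      }
      best_pdev[r] <- 100 * (base_fit$deviance - best_dev) / null_dev
    }
  })
  structure(list(
    spurious_probability = mean(best_pdev > true_pdev),
    true_term = true_term,
    true_pct_deviance = true_pdev,
    replicate_pct_deviance = best_pdev,
    reps = reps,
    seed = seed
  ), class = "randomization_report")
}

#' @export
print.randomization_report <- function(x, ...) {
  cat(sprintf("<randomization_report> %s: %.2f%% deviance; spurious probability %.3f (%d reps)\n",
              x$true_term, x$true_pct_deviance, x$spurious_probability, x$reps))
  invisible(x)
}
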