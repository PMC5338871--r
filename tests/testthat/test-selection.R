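test_that("species filtering applies the strict n > 90 spawner rule and valid sets", {
  mk <- function(species, n_spawn, n_nonspawn, sets_of_3 = 0) {
    n <- n_spawn + n_nonspawn
    data.frame(set_id = c(sprintf("%s_%03d", species, seq_len(n - 3 * sets_of_3)),
                          rep(sprintf("%s_V%02d", species, seq_len(max(sets_of_3, 1))),
                              length.out = 3 * sets_of_3)),
               species = species,
               spawning = rep(c(1L, 0L), c(n_spawn, n_nonspawn)))
  }
  rec <- rbind(mk("A", 90, 50), mk("B", 91, 50), mk("C", 10, 5, sets_of_3 = 2))
  res <- filter_modelable(rec)
  expect_false(res$modelable[res$species == "A"])  # exactly 90: excluded
  expect_true(res$modelable[res$species == "B"])   # 91: included
  expect_equal(res$valid_sets[res$species == "C"], 2)
  # a set with exactly 3 sampled fish counts as a Valid Set
  rec3 <- data.frame(set_id = "X1", species = "D", spawning = c(1L, 0L, 0L))
  expect_equal(filter_modelable(rec3)$valid_sets, 1)
})

test_that("the correlation screen blocks strictly above 0.60", {
  # engineered pair with sample correlation exactly 0.6
  x <- rep(c(1, 2, 3, 4, 5), 30)
  y <- rep(c(3, 1, 2, 5, 4), 30)
  expect_equal(cor(x, y), 0.6, tolerance = 1e-12)
  d <- make_design(data.frame(a = x, b = y, spawning = rep(0:1, 75)), c("a", "b"))
  scr <- correlation_screen(d)
  expect_equal(nrow(scr$blocked), 0)  # 0.60 exactly is allowed

  d2 <- make_design(data.frame(a = x, b = x + rnorm(150, 0, 0.1),
                               spawning = rep(0:1, 75)), c("a", "b"))
  scr2 <- correlation_screen(d2)
  expect_equal(nrow(scr2$blocked), 1)  # near-duplicate blocked
  expect_gt(scr2$matrix["a", "b"], 0.99)

  # independent draws stay far below the threshold
  set.seed(1)
  d3 <- make_design(data.frame(a = runif(10000), b = runif(10000),
                               spawning = rep(0:1, 5000)), c("a", "b"))
  scr3 <- correlation_screen(d3)
  expect_lt(scr3$matrix["a", "b"], 0.05)

  # zero-variance columns are excluded with a warning
  d4 <- make_design(data.frame(a = x, b = rep(2, 150), spawning = rep(0:1, 75)),
                    c("a", "b"))
  expect_warning(scr4 <- correlation_screen(d4), "zero-variance")
  expect_false("b" %in% rownames(scr4$matrix))
})

test_that("factor pairs are screened by Cramer's V", {
  set.seed(2)
  f1 <- factor(sample(letters[1:3], 400, replace = TRUE))
  d <- make_design(data.frame(a = f1, b = f1, c = factor(sample(letters[1:3], 400, TRUE)),
                              spawning = rep(0:1, 200)), c("a", "b", "c"))
  scr <- correlation_screen(d)
  expect_equal(scr$matrix["a", "b"], 1, tolerance = 1e-9)
  expect_lt(scr$matrix["a", "c"], 0.3)
  expect_true(any(scr$blocked$term1 == "a" & scr$blocked$term2 == "b"))
})

test_that("forward stepwise prefers true effects and respects hierarchy", {
  # the true predictor is selected first in nearly every replicate
  first_hits <- 0
  n_sim <- 30
  for (s in seq_len(n_sim)) {
    set.seed(1000 + s)
    n <- 2000
    df <- data.frame(x_true = rnorm(n), n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
    df$spawning <- rbinom(n, 1, plogis(1.0 * df$x_true))
    d <- make_design(df, c("x_true", "n1", "n2", "n3"))
    sw <- forward_stepwise(d, candidates = c("x_true", "n1", "n2", "n3"),
                           random = FALSE)
    if (nrow(sw$path) >= 2 && sw$path$added[2] == "x_true") first_hits <- first_hits + 1
  }
  expect_gte(first_hits, ceiling(0.95 * n_sim) - 2)

  # stepwise AIC path is non-increasing
  set.seed(3)
  n <- 1500
  df <- data.frame(a = rnorm(n), b = rnorm(n))
  df$spawning <- rbinom(n, 1, plogis(0.6 * df$a - 0.4 * df$b))
  sw <- forward_stepwise(make_design(df, c("a", "b")), candidates = c("a", "b"),
                         random = FALSE)
  expect_true(all(diff(sw$path$aic) <= 0))
  # visited models are ranked by AIC
  expect_true(!is.unsorted(sw$models$aic))

  # interactions require their margins unless overridden
  w <- make_world(seed = 81, n_years = 3, n_sets_per_year = 30)
  d2 <- build_design(w$survey$records, terms = c("latitude", "month", "lat_x_month"))
  sw2 <- forward_stepwise(d2, candidates = c("lat_x_month", "latitude", "month"),
                          random = FALSE)
  steps <- sw2$path$added[-1]
  pos_int <- match("lat_x_month", steps)
  if (!is.na(pos_int)) {
    expect_true(all(match(c("latitude", "month"), steps) < pos_int))
  }
  expect_error(spawn_glmm(d2, terms = "lat_x_month"), "requires margin")
  expect_silent(suppressWarnings(spawn_glmm(d2, terms = "lat_x_month",
                                            hierarchy_override = TRUE, random = FALSE)))
})

test_that("all-noise stepwise keeps the AIC false-inclusion rate in check", {
  inclusions <- 0
  n_sim <- 60
  n_cand <- 4
  for (s in seq_len(n_sim)) {
    set.seed(2000 + s)
    n <- 1000
    df <- data.frame(n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n), n4 = rnorm(n))
    df$spawning <- rbinom(n, 1, 0.35)
    sw <- forward_stepwise(make_design(df, paste0("n", 1:4)),
                           candidates = paste0("n", 1:4), random = FALSE)
    inclusions <- inclusions + length(sw$best_terms)
  }
  expect_lte(inclusions / (n_sim * n_cand), 0.30)
})

test_that("the ROC threshold rule matches brute force and the quoted example", {
  # labels (0,0,1,1), scores (.1,.2,.8,.9): any t in (0.2, 0.8] is optimal;
  # the lowest observed-score candidate achieving the max is 0.8
  expect_equal(roc_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 0.8)
  set.seed(4)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    scores <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_threshold(scores, labels), brute_threshold(scores, labels))
  }
})

test_that("cross-validation reports sane pooled metrics and fold partitions", {
  set.seed(5)
  n <- 600
  df <- data.frame(x = rnorm(n), year = 2001)
  df$spawning <- rbinom(n, 1, plogis(1.2 * df$x))
  d <- make_design(df, "x")
  cv <- crossvalidate(d, "x", k = 10, seed = 99, random = FALSE)
  expect_true(cv$auc > 50 && cv$auc <= 100)
  expect_equal(sort(unique(cv$folds)), 1:10)
  expect_equal(length(cv$folds), n)
  # every row in exactly one fold, stratified by class
  expect_true(all(table(cv$folds) >= n / 10 - 2))
  expect_equal(cv$grade, grade_auc(cv$auc))
  # AUC agrees with an independent implementation on the pooled predictions
  skip_if_not_installed("pROC")
  p <- suppressWarnings(predict(spawn_glmm(d, random = FALSE), se.fit = FALSE)$fit)
  expect_equal(100 * auc_rank(p, df$spawning),
               100 * as.numeric(suppressMessages(pROC::auc(df$spawning, p))),
               tolerance = 1e-8)
})

test_that("AUC grades map by the published intervals with boundaries up", {
  expect_equal(grade_auc(81.93), "good")       # Gray Triggerfish
  expect_equal(grade_auc(90.31), "excellent")  # White Grunt
  expect_equal(grade_auc(67.99), "poor")       # Vermilion Snapper, fine scale
  expect_equal(grade_auc(c(90, 80, 70, 69.999)),
               c("excellent", "good", "fair", "poor"))
  expect_error(grade_auc(101), "within")
  # monotone in AUC
  g <- factor(grade_auc(seq(0, 100, by = 0.5)),
              levels = c("poor", "fair", "good", "excellent"), ordered = TRUE)
  expect_true(!is.unsorted(g))
})

test_that("randomization permutations preserve marginals and default to 500 reps", {
  expect_equal(eval(formals(randomization_test)$reps), 500)
  set.seed(6)
  n <- 800
  df <- data.frame(x = rnorm(n), b1 = rnorm(n), b2 = rnorm(n))
  df$spawning <- rbinom(n, 1, plogis(0.8 * df$x + 0.5 * df$b1))
  d <- make_design(df, c("x", "b1", "b2"))
  rt <- randomization_test(d, base_terms = "x", candidates = c("b1", "b2"),
                           true_term = "b1", reps = 30, seed = 7, random = FALSE)
  expect_equal(length(rt$replicate_pct_deviance), 30)
  expect_true(rt$spurious_probability >= 0 && rt$spurious_probability <= 1)
  expect_gt(rt$true_pct_deviance, 0)
  expect_error(randomization_test(d, "x", c("b1", "b2"), "b1", reps = 0), "reps")
})
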