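# Two-class Gaussian feature sets with a controllable mean gap (in SD
# units) for exercising the classifier stack without the signal pipeline.
sim_features <- function(n_per = 24, gap = 4, p_inform = 2, p_noise = 2,
                         seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  y <- rep(c("PSH", "noPSH"), each = n_per)
  x <- matrix(rnorm(n * (p_inform + p_noise)), n)
  for (j in seq_len(p_inform)) {
    x[y == "PSH", j] <- x[y == "PSH", j] + gap
  }
  colnames(x) <- c(paste0("inf", seq_len(p_inform), recycle0 = TRUE),
                   paste0("noise", seq_len(p_noise), recycle0 = TRUE))
  list(x = as.data.frame(x), y = y)
}

test_that("metrics satisfy their algebraic identities over a count sweep", {
  for (tp in c(0, 3, 16, 24)) {
    for (fn in c(0, 5, 8)) {
      for (fp in c(0, 2, 24)) {
        for (tn in c(1, 17, 24)) {
          if (tp + fn == 0) next
          m <- compute_metrics(tp, fn, fp, tn)
          expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
          expect_equal(m$misclassification_rate, (fn + fp) / (tp + fn + fp + tn))
          if (tp + fp > 0 && (m$precision + m$sensitivity) > 0) {
            expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                           (m$precision + m$sensitivity))
          }
          expect_true(all(unlist(m[c("sensitivity", "specificity",
                                     "balanced_accuracy")]) >= 0))
          expect_true(all(unlist(m[c("sensitivity", "specificity",
                                     "balanced_accuracy")]) <= 1))
        }
      }
    }
  }
  expect_true(is.na(compute_metrics(0, 10, 0, 10)$f1)) # precision undefined
  expect_error(compute_metrics(0, 0, 5, 5), "both classes")
})

test_that("the printed-performance confusion matrices are reproduced", {
  pre10 <- compute_metrics(tp = 16, fn = 8, fp = 0, tn = 24)
  expect_equal(round(100 * pre10$sensitivity), 67)
  expect_equal(round(100 * pre10$specificity), 100)
  expect_equal(round(100 * pre10$balanced_accuracy), 83)
  expect_equal(round(100 * pre10$f1), 80)

  perfect <- compute_metrics(24, 0, 0, 24)
  expect_equal(perfect$balanced_accuracy, 1)
  expect_equal(perfect$misclassification_rate, 0)

  inverted <- compute_metrics(0, 24, 24, 0)
  expect_equal(inverted$balanced_accuracy, 0)
})

test_that("random-forest ranking finds the informative feature", {
  top_hits <- vapply(1:10, function(s) {
    d <- sim_features(n_per = 20, gap = 3, p_inform = 1, p_noise = 4, seed = s)
    sel <- select_features(d$x, d$y, seed = s)
    sel$ranking$feature[1] == "inf1"
  }, logical(1))
  expect_gte(mean(top_hits), 0.95)
})

test_that("all-noise features share importance roughly uniformly", {
  shares <- replicate(5, {
    d <- sim_features(n_per = 20, gap = 0, p_inform = 0, p_noise = 5,
                      seed = sample.int(1000, 1))
    sel <- select_features(d$x, d$y, seed = 3)
    max(sel$ranking$importance) / sum(sel$ranking$importance)
  })
  expect_lt(mean(shares), 2 / 5)
})

test_that("cross-validation separates well-separated classes perfectly", {
  d <- sim_features(gap = 4, seed = 2)
  cv <- crossvalidate(d$x, d$y, cost_c = 2, gamma = 0.1, k = 10, seed = 5)
  expect_equal(cv$validation$misclassification_rate, 0)
  expect_equal(cv$validation$balanced_accuracy, 1)
})

test_that("constant features produce chance-level validation accuracy", {
  set.seed(8)
  bas <- vapply(1:10, function(s) {
    y <- rep(c("PSH", "noPSH"), each = 20)
    x <- data.frame(a = rnorm(40), b = rnorm(40))
    crossvalidate(x, y, cost_c = 2, gamma = 0.5, k = 10,
                  seed = s)$validation$balanced_accuracy
  }, numeric(1))
  expect_gte(mean(bas), 0.35)
  expect_lte(mean(bas), 0.65)
})

test_that("fold construction is stratified and bounded", {
  y <- rep(c("PSH", "noPSH"), each = 24)
  fold <- pshhrv:::stratified_folds(y, 10, seed = 1)
  sizes <- table(fold)
  expect_true(all(sizes >= 4 & sizes <= 5))
  for (f in 1:10) expect_setequal(unique(y[fold == f]), c("PSH", "noPSH"))
  expect_error(
    crossvalidate(sim_features(n_per = 5)$x, rep(c("PSH", "noPSH"), each = 5),
                  k = 10),
    "leave-one-out"
  )
})

test_that("grid search finds perfect configurations on separable data", {
  d <- sim_features(gap = 3, p_inform = 4, p_noise = 0, seed = 3)
  gs <- grid_search(d$x, d$y, seed = 7)
  expect_equal(gs$n_models, 100)
  n_perfect <- sum(gs$results$validation_misclassification == 0)
  expect_gte(n_perfect, 45)
  expect_equal(gs$best$validation_balanced_accuracy, 1)
  expect_true(gs$best$cost_c >= 0.5 && gs$best$cost_c <= 10)
  expect_true(gs$best$gamma >= 0.01 && gs$best$gamma <= 10)
})

test_that("a duplicated feature column is equivalent to doubling gamma", {
  d <- sim_features(n_per = 12, gap = 3, p_inform = 1, p_noise = 0, seed = 4)
  x1 <- d$x
  x2 <- cbind(d$x, inf1_copy = d$x$inf1)
  for (g in c(0.05, 0.2, 1)) {
    cv1 <- crossvalidate(x1, d$y, cost_c = 2, gamma = 2 * g, k = 6, seed = 9)
    cv2 <- crossvalidate(x2, d$y, cost_c = 2, gamma = g, k = 6, seed = 9)
    expect_equal(cv2$validation$balanced_accuracy,
                 cv1$validation$balanced_accuracy, tolerance = 1e-9)
    expect_equal(cv2$confusion, cv1$confusion)
  }
})

test_that("permuted labels drop the best model to chance", {
  bas <- vapply(1:5, function(s) {
    d <- sim_features(n_per = 12, gap = 3, seed = s)
    set.seed(s + 1000)
    y_perm <- sample(d$y)
    gs <- grid_search(d$x, y_perm, grid_size = 3, seed = s)
    gs$best$validation_balanced_accuracy
  }, numeric(1))
  expect_lt(abs(mean(bas) - 0.5), 0.15)
})

test_that("search results are deterministic for a fixed fold seed", {
  d <- sim_features(gap = 2, seed = 6)
  g1 <- grid_search(d$x, d$y, grid_size = 3, seed = 11)
  g2 <- grid_search(d$x, d$y, grid_size = 3, seed = 11)
  expect_identical(g1$results, g2$results)
})

test_that("ablating the only informative feature collapses accuracy", {
  d <- sim_features(n_per = 20, gap = 4, p_inform = 1, p_noise = 3, seed = 12)
  ab <- feature_ablation(d$x, d$y, cost_c = 2, gamma = 0.2, seed = 13)
  drop_inf <- ab$balanced_accuracy[ab$ablated == "inf1"]
  expect_lt(drop_inf, 0.7)
  others <- ab$balanced_accuracy[!(ab$ablated %in% c("full", "inf1"))]
  expect_true(all(abs(others - ab$balanced_accuracy[ab$ablated == "full"]) < 0.1))
})

test_that("removing one copy of a duplicated informative feature is free", {
  d <- sim_features(n_per = 16, gap = 4, p_inform = 1, p_noise = 1, seed = 14)
  x <- cbind(d$x, inf1_copy = d$x$inf1)
  ab <- feature_ablation(x, d$y, cost_c = 2, gamma = 0.2, seed = 15)
  full_ba <- ab$balanced_accuracy[ab$ablated == "full"]
  expect_equal(ab$balanced_accuracy[ab$ablated == "inf1_copy"], full_ba,
               tolerance = 1e-9)
})

test_that("standardization leaks nothing from validation folds", {
  # a feature whose value is a deterministic copy of the (permuted) label
  # must not yield above-chance validation accuracy, which it would if
  # standardization or fitting saw the held-out fold
  bas <- vapply(1:5, function(s) {
    set.seed(s)
    y <- sample(rep(c("PSH", "noPSH"), each = 15))
    x <- data.frame(canary = rnorm(30), junk = rnorm(30))
    crossvalidate(x, y, cost_c = 5, gamma = 1, k = 5,
                  seed = s)$validation$balanced_accuracy
  }, numeric(1))
  expect_lt(mean(bas), 0.7)
})
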