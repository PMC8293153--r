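test_that("augmentation yields balanced samples with the expected counts", {
  ph <- generate_phantom(phantom_spec(n_subunits = 3, seed = 41,
                                      grid_shape = c(24L, 24L, 24L),
                                      blob_radius = c(2.5, 4)))
  set.seed(5)
  s <- augment_samples(ph, source_map = "m1")
  expect_equal(nrow(s), 20L)
  expect_equal(sum(s$label == "good"), 10L)
  expect_equal(sum(s$label == "bad"), 10L)
  # every good sample is the ground truth with one two-way split:
  # segment count must be exactly truth + 1
  good <- s[s$label == "good", ]
  expect_true(all(good$f001 == n_segments(ph$truth) + 1))
  # over-segmentation is typical (not guaranteed) for the bad class: judge
  # it corpus-wide rather than on a single map
  corpus_samples <- shared_samples()
  truth_counts <- vapply(shared_corpus(),
                         function(p) n_segments(p$truth), integer(1))
  expect_gt(stats::median(corpus_samples$f001[corpus_samples$label == "bad"]),
            stats::median(truth_counts))
})

test_that("a separable feature set trains to near-perfect held-out AUC", {
  s <- separable_samples()
  m <- train_fitness_model(s, family = "rf",
                           grid = list(n_estimators = 100L,
                                       max_features = "auto"),
                           cv_folds = 3L, seed = 2)
  expect_gt(m$cv_auc, 0.99)
  # scoring the training set reproduces fit-time behaviour deterministically
  X <- as.matrix(s[, sprintf("f%03d", 1:121)])
  s1 <- fitness_score(m, X)
  s2 <- fitness_score(m, X)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  # good-like feature vector outscores an over-segmented one
  expect_gt(fitness_score(m, as.numeric(X[1, ])),
            fitness_score(m, as.numeric(X[nrow(X), ])))
})

test_that("permuting the labels destroys the signal (chance-level AUC)", {
  s <- separable_samples()
  s$label <- withr::with_seed(12, sample(s$label))
  m <- train_fitness_model(s, family = "rf",
                           grid = list(n_estimators = 100L,
                                       max_features = "auto"),
                           cv_folds = 3L, seed = 2)
  expect_lt(abs(m$cv_auc - 0.5), 0.2)
})

test_that("all four model families train behind the same interface", {
  s <- separable_samples(n_per_class = 30L)
  for (fam in c("logistic", "svm", "mlp")) {
    m <- train_fitness_model(s, family = fam, cv_folds = 3L, seed = 4)
    expect_s3_class(m, "fitness_model")
    expect_gt(m$cv_auc, 0.9)
    sc <- fitness_score(m, as.numeric(as.matrix(s[1, sprintf("f%03d",
                                                             1:121)])))
    expect_true(sc >= 0 && sc <= 1)
  }
})

test_that("grid search selects the best-scoring grid point", {
  s <- separable_samples(n_per_class = 25L)
  m <- train_fitness_model(s, family = "logistic",
                           grid = list(C = c(0.01, 1, 100)), cv_folds = 3L,
                           seed = 6)
  expect_equal(m$cv_auc, max(m$grid_results$cv_auc))
  expect_equal(nrow(m$grid_results), 3L)
  expect_equal(nrow(tidy(m)), 3L)
  expect_equal(glance(m)$n_grid_points, 3L)
})

test_that("single-class input is rejected", {
  s <- separable_samples(n_per_class = 10L)
  expect_error(train_fitness_model(s[s$label == "good", ], family = "rf"),
               "class")
  m <- train_fitness_model(s, family = "rf",
                           grid = list(n_estimators = 50L,
                                       max_features = "auto"),
                           cv_folds = 2L, seed = 1)
  expect_error(evaluate_roc(m, s[s$label == "bad", ]), "class")
})

test_that("ROC/AUC match the rank-statistic oracle and the known extremes", {
  # oracle equivalence on random scores
  withr::with_seed(55, {
    for (trial in 1:10) {
      n <- 50L
      y <- sample(c(0L, 1L), n, replace = TRUE, prob = c(0.5, 0.5))
      if (length(unique(y)) < 2L) next
      sc <- runif(n)
      expect_equal(evoseg:::.auc_trapezoid(sc, y), oracle_auc(sc, y),
                   tolerance = 1e-12)
    }
  })
  # perfect scorer
  y <- rep(c(0L, 1L), each = 10L)
  expect_equal(evoseg:::.auc_trapezoid(c(runif(10, 0, 0.4),
                                         runif(10, 0.6, 1)), y), 1.0)
  # constant scorer
  expect_equal(evoseg:::.auc_trapezoid(rep(0.3, 20), y), 0.5)
})

test_that("models round-trip through disk with a provenance sidecar", {
  s <- separable_samples(n_per_class = 15L)
  m <- train_fitness_model(s, family = "rf",
                           grid = list(n_estimators = 50L,
                                       max_features = "auto"),
                           cv_folds = 2L, seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_fitness_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$family, "rf")
  m2 <- load_fitness_model(path)
  X <- as.matrix(s[, sprintf("f%03d", 1:121)])
  expect_identical(fitness_score(m, X), fitness_score(m2, X))
})
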