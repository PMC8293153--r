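# Shared fixtures, built in code. Expensive objects (phantom dataset, trained
# fitness model) are created lazily once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

# small noisy two-blob phantom for generic segmentation tests
tiny_phantom <- function() {
  fixture("tiny_phantom", function()
    generate_phantom(phantom_spec(n_subunits = 2, grid_shape = c(20L, 20L, 20L),
                                  blob_radius = c(2, 3), seed = 101)))
}

# a clean map with two well-separated Gaussian blobs (known two maxima)
two_blob_map <- function() {
  d <- c(16L, 16L, 16L)
  g1 <- outer(outer(exp(-0.5 * ((1:16 - 5) / 1.6)^2),
                    exp(-0.5 * ((1:16 - 8) / 1.6)^2)),
              exp(-0.5 * ((1:16 - 8) / 1.6)^2))
  g2 <- outer(outer(exp(-0.5 * ((1:16 - 12) / 1.6)^2),
                    exp(-0.5 * ((1:16 - 8) / 1.6)^2)),
              exp(-0.5 * ((1:16 - 8) / 1.6)^2))
  density_map(g1 + g2, threshold = 0.15)
}

# the 8-voxel worked example: truth = two 4-voxel slabs, prediction swaps one
# voxel across the boundary (per-pair IoU 3/5, H 0.75, P 2, C 2)
toy_eight <- function() {
  truth <- array(0L, c(8L, 1L, 1L))
  truth[1:4, 1, 1] <- 1L
  truth[5:8, 1, 1] <- 2L
  pred <- array(0L, c(8L, 1L, 1L))
  pred[c(1, 2, 3, 5), 1, 1] <- 1L
  pred[c(4, 6, 7, 8), 1, 1] <- 2L
  list(pred = label_map(pred), truth = label_map(truth))
}

# modest phantom corpus + random-forest fitness model shared by the
# optimizer tests (kept small; the acceptance suite builds the full corpus)
shared_corpus <- function() {
  fixture("shared_corpus", function() generate_dataset(12, seed = 4242))
}

shared_samples <- function() {
  fixture("shared_samples", function()
    augment_dataset(shared_corpus(), seed = 7))
}

shared_model <- function() {
  fixture("shared_model", function()
    train_fitness_model(shared_samples(), family = "rf",
                        grid = list(n_estimators = 200L,
                                    max_features = "auto"),
                        cv_folds = 3L, seed = 1))
}

# clearly separable synthetic feature tibble: "good" samples have few
# segments, "bad" many — mimicking the real augmentation contrast
separable_samples <- function(n_per_class = 40L, seed = 99) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(2L * n_per_class), function(i) {
      good <- i <= n_per_class
      k <- if (good) sample(2:5, 1L) else sample(30:60, 1L)
      x <- numeric(FEATURE_LENGTH)
      x[1L] <- k
      props <- runif(k)
      props <- props / sum(props)
      x[2L * seq_len(k)] <- sort(props, decreasing = TRUE)
      x[2L * seq_len(k) + 1L] <- 1
      out <- as.list(stats::setNames(x, sprintf("f%03d", 1:FEATURE_LENGTH)))
      out$label <- if (good) "good" else "bad"
      out$source_map <- sprintf("synthetic%02d", i)
      tibble::as_tibble_row(out)
    })
    do.call(rbind, rows)
  })
}

# the full 73-map synthetic corpus and its augmented samples / trained
# fitness model, shared by the acceptance suite (built once, ~3 min)
acceptance_corpus <- function() {
  fixture("acceptance_corpus", function() generate_dataset(73, seed = 20210601))
}

acceptance_samples <- function() {
  fixture("acceptance_samples", function()
    augment_dataset(acceptance_corpus(), seed = 73))
}

acceptance_model <- function() {
  fixture("acceptance_model", function()
    train_fitness_model(acceptance_samples(), family = "rf",
                        grid = list(n_estimators = 400L,
                                    max_features = "auto"),
                        cv_folds = 5L, seed = 11))
}

# a scorer whose value strictly increases on every call (never converges)
increasing_scorer <- function() {
  counter <- new.env(parent = emptyenv())
  counter$i <- 0
  function(features) {
    counter$i <- counter$i + 1
    counter$i / 1e9
  }
}
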