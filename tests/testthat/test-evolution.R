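test_that("initial population has 30 scored individuals within bounds", {
  ph <- tiny_phantom()
  pop <- init_population(ph$map, ga_config(), model = 0.5, seed = 3)
  expect_length(pop, 30L)
  for (p in pop) {
    expect_false(is.na(p$fitness))
    expect_true(p$sigma >= 1 && p$sigma <= 4)
    expect_true(p$steps %in% 1:4)
  }
  pop2 <- init_population(ph$map, ga_config(), model = 0.5, seed = 3)
  expect_identical(lapply(pop, function(p) p$labels$labels),
                   lapply(pop2, function(p) p$labels$labels))
})

test_that("parent selection is fitness-weighted with a uniform fallback", {
  ph <- tiny_phantom()
  base <- watershed_segment(ph$map)
  mk <- function(fit) individual(base, fitness = fit)
  # one dominant individual takes nearly all parent slots
  pop <- c(list(mk(1.0)), replicate(9, mk(1e-9), simplify = FALSE))
  withr::with_seed(11, {
    picks <- unlist(replicate(100, {
      parents <- select_parents(pop, ga_config())
      vapply(parents, function(p) p$fitness, numeric(1))
    }, simplify = FALSE))
  })
  expect_gt(mean(picks == 1.0), 0.99)
  # all-equal fitness: approximately uniform frequencies
  pop_eq <- replicate(5, mk(0.4), simplify = FALSE)
  for (i in seq_along(pop_eq)) pop_eq[[i]]$steps <- i   # tag identity
  withr::with_seed(12, {
    tags <- unlist(replicate(200, vapply(select_parents(pop_eq, ga_config()),
                                         function(p) p$steps, integer(1)),
                             simplify = FALSE))
  })
  freq <- tabulate(tags, 5) / length(tags)
  expect_true(all(abs(freq - 0.2) < 0.03))
  # 30 parents = 15 round-robin pairs under the default configuration
  expect_length(select_parents(pop_eq, ga_config()), 30L)
  expect_error(select_parents(list(), ga_config()), "empty")
})

test_that("crossover of identical parents reproduces the parent partition", {
  ph <- tiny_phantom()
  a <- withr::with_seed(5, random_segmentation(ph$map))
  off <- withr::with_seed(6, crossover(a, a))
  expect_equal(matched_iou(off$labels, a$labels, "all")$value, 1.0)
})

test_that("crossover covers the foreground with subsets of parent segments", {
  ph <- tiny_phantom()
  a <- withr::with_seed(7, random_segmentation(ph$map))
  b <- withr::with_seed(8, random_segmentation(ph$map))
  mask <- a$labels$labels > 0L
  for (s in 1:10) {
    off <- withr::with_seed(100 + s, crossover(a, b))
    expect_true(all(off$labels$labels[mask] > 0L))
    expect_true(all(off$labels$labels[!mask] == 0L))
    expect_lte(n_segments(off$labels),
               n_segments(a$labels) + n_segments(b$labels))
  }
  # mismatched foregrounds are rejected
  other <- individual(label_map(array(1L, dim(mask))))
  expect_error(crossover(a, other), "foreground")
})

test_that("crossover on the 4-voxel toy only reaches enumerable offspring", {
  d <- c(4L, 1L, 1L)
  a <- individual(label_map(array(c(1L, 1L, 2L, 2L), d)))
  b <- individual(label_map(array(c(1L, 2L, 2L, 2L), d)))
  segs <- list(c(1L, 2L), c(3L, 4L), 1L, c(2L, 3L, 4L))
  # oracle: exhaustively stamp segments in every draw order
  stamp <- function(order) {
    off <- integer(4)
    nxt <- 0L
    for (s in order) {
      free <- segs[[s]][off[segs[[s]]] == 0L]
      if (length(free)) {
        nxt <- nxt + 1L
        off[free] <- nxt
      }
      if (all(off > 0L)) break
    }
    off
  }
  canon <- function(v) match(v, unique(v))
  reachable <- unique(apply(oracle_perms(4L), 1L,
                            function(o) paste(canon(stamp(o)),
                                              collapse = "")))
  for (s in 1:60) {
    off <- withr::with_seed(s, crossover(a, b))
    got <- paste(canon(as.vector(off$labels$labels)), collapse = "")
    expect_true(got %in% reachable)
    # every offspring segment is a subset of some parental segment
    for (k in seq_len(n_segments(off$labels))) {
      vox <- which(off$labels$labels == k)
      expect_true(any(vapply(segs, function(sg) all(vox %in% sg), TRUE)))
    }
  }
})

test_that("merge mutation unites one adjacent pair and handles degeneracy", {
  d <- c(6L, 2L, 1L)
  lab <- array(0L, d)
  lab[1:2, , 1] <- 1L
  lab[3:4, , 1] <- 2L
  lab[5:6, , 1] <- 3L
  ind <- individual(label_map(lab))
  m <- withr::with_seed(3, mutate_merge(ind))
  expect_equal(n_segments(m$labels), 2L)
  expect_identical(m$labels$labels > 0L, lab > 0L)   # voxel union preserved
  # merged piece is exactly the union of two old segments
  sizes <- sort(segment_volumes(m$labels)$voxels)
  expect_true(identical(sizes, c(4L, 8L)) || identical(sizes, c(4L, 8L)))
  # single segment: identity
  one <- individual(label_map(array(1L, c(2L, 2L, 1L))))
  expect_equal(n_segments(mutate_merge(one)$labels), 1L)
  # disconnected-only segments: identity (no adjacent pair)
  iso <- array(0L, c(5L, 1L, 1L))
  iso[1, 1, 1] <- 1L
  iso[3, 1, 1] <- 2L
  iso[5, 1, 1] <- 3L
  expect_equal(n_segments(mutate_merge(individual(label_map(iso)))$labels),
               3L)
})

test_that("split mutation partitions one segment and keeps its voxel set", {
  # two blobs wrongly merged into one segment: a fine split separates them
  m <- two_blob_map()
  lab <- watershed_segment(m)$labels
  merged <- individual(label_map(array(as.integer(lab > 0L), dim(lab))))
  got <- withr::with_seed(21, mutate_split(merged, m))
  expect_gte(n_segments(got$labels), 2L)
  expect_identical(got$labels$labels > 0L, lab > 0L)
  # single-voxel segment cannot split: identity after retries
  tiny <- array(0L, c(3L, 3L, 1L))
  tiny[2, 2, 1] <- 1L
  ind <- individual(label_map(tiny))
  out <- withr::with_seed(2, mutate_split(ind, two_blob_map()))
  expect_identical(out$labels$labels, tiny)
})

test_that("offspring respect the crossover/copy and mutation switches", {
  ph <- tiny_phantom()
  a <- withr::with_seed(31, random_segmentation(ph$map))
  b <- withr::with_seed(32, random_segmentation(ph$map))
  # no crossover, no mutation: offspring equals one parent
  cfg0 <- ga_config(p_crossover = 0, p_mutation = 0)
  off <- withr::with_seed(33, make_offspring(list(a, b), cfg0, ph$map))
  same_a <- identical(off$labels$labels, a$labels$labels)
  same_b <- identical(off$labels$labels, b$labels$labels)
  expect_true(same_a || same_b)
  expect_false(attr(off, "crossed"))
  expect_identical(attr(off, "mutation"), "none")
})

test_that("stopping rules fire exactly as configured", {
  ph <- tiny_phantom()
  # constant fitness: no generation ever improves; the loop must stop after
  # exactly `patience` non-improving generations
  cfg <- ga_config(max_iterations = 30L, patience = 6L)
  run <- run_evolution(ph$map, model = 0.5, config = cfg, seed = 13)
  expect_identical(run$stopping_reason, "patience")
  expect_equal(nrow(run$log), 6L)
  # strictly increasing scorer: never stalls, runs to max_iterations
  cfg2 <- ga_config(max_iterations = 8L, patience = 5L)
  run2 <- run_evolution(ph$map, model = increasing_scorer(), config = cfg2,
                        seed = 14)
  expect_identical(run2$stopping_reason, "max_iterations")
  expect_equal(nrow(run2$log), 8L)
})

test_that("elitist replacement gives a non-decreasing best-score trajectory", {
  ph <- tiny_phantom()
  cfg <- ga_config(max_iterations = 6L, patience = 6L,
                   replacement = "elitist")
  run <- run_evolution(ph$map, model = shared_model(), config = cfg,
                       truth = ph$truth, seed = 15)
  expect_true(all(diff(run$log$best_score) >= 0))
  expect_true(all(diff(run$log$best_ever) >= 0))
  expect_equal(nrow(run$log), 6L)
})

test_that("runs are reproducible and keep full foreground coverage", {
  ph <- tiny_phantom()
  cfg <- ga_config(max_iterations = 4L, patience = 4L)
  r1 <- run_evolution(ph$map, model = shared_model(), config = cfg, seed = 16)
  r2 <- run_evolution(ph$map, model = shared_model(), config = cfg, seed = 16)
  expect_identical(r1$best$labels$labels, r2$best$labels$labels)
  expect_equal(r1$log, r2$log)
  mask <- foreground_mask(ph$map)
  expect_true(all(r1$best$labels$labels[mask] > 0L))
  # tidy/glance accessors
  expect_equal(nrow(tidy(r1)), 4L)
  expect_identical(glance(r1)$stopping_reason, r1$stopping_reason)
})
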