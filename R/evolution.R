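# The evolutionary segmentation loop. A population of random watershed
# segmentation states is iteratively improved: fitness-weighted round-robin
# parent selection, segment-superposition crossover, merge/split mutation,
# replacement (fully generational or elitist) and patience-based stopping.

#' One segmentation state of the evolutionary population
#'
#' @param labels A [label_map()] covering the foreground.
#' @param sigma,steps Watershed provenance (smoothing width and grouping
#'   rounds that produced the state), `NA` for derived offspring.
#' @param fitness Cached fitness in \[0, 1\], `NA` until scored.
#' @return An `evoseg_individual`.
#' @export
individual <- function(labels, sigma = NA_real_, steps = NA_integer_,
                       fitness = NA_real_) {
  stopifnot(inherits(labels, "label_map"))
  structure(list(labels = labels, sigma = as.numeric(sigma),
                 steps = as.integer(steps), fitness = as.numeric(fitness)),
            class = "evoseg_individual")
}

#' @export
print.evoseg_individual <- function(x, ...) {
  cat(sprintf("<evoseg_individual> %d segment(s), fitness %s, (sigma=%s, s=%s)\n",
              n_segments(x$labels),
              if (is.na(x$fitness)) "unset" else sprintf("%.3f", x$fitness),
              if (is.na(x$sigma)) "-" else sprintf("%.2f", x$sigma),
              if (is.na(x$steps)) "-" else x$steps))
  invisible(x)
}

#' Configuration of the evolutionary optimizer
#'
#' Defaults are the published operating point: population 30, 30 parents
#' combined into 15 offspring per generation, crossover probability 0.9,
#' mutation probability 0.1, stop at 200 iterations or after 20 consecutive
#' iterations without a higher fitness.
#'
#' @param population_size Individuals kept per generation.
#' @param parents_per_generation Parents sampled each generation (paired
#'   round-robin, so two parents per offspring).
#' @param offspring_per_generation Offspring created per generation.
#' @param p_crossover Probability an offspring is a crossover rather than a
#'   direct copy of one parent.
#' @param p_mutation Probability an offspring is mutated (merge or split,
#'   equally likely).
#' @param max_iterations Hard generation cap.
#' @param patience Consecutive non-improving generations before stopping.
#' @param replacement `"generational"` (whole population replaced by
#'   offspring plus fresh random states) or `"elitist"` (top-fitness
#'   individuals are retained).
#' @return A `ga_config` object.
#' @export
ga_config <- function(population_size = 30L, parents_per_generation = 30L,
                      offspring_per_generation = 15L, p_crossover = 0.9,
                      p_mutation = 0.1, max_iterations = 200L, patience = 20L,
                      replacement = c("generational", "elitist")) {
  replacement <- match.arg(replacement)
  stopifnot(population_size >= 1, parents_per_generation >= 2,
            parents_per_generation %% 2 == 0,
            offspring_per_generation >= 1,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1,
            max_iterations >= 1, patience >= 1, patience <= max_iterations)
  structure(list(population_size = as.integer(population_size),
                 parents_per_generation = as.integer(parents_per_generation),
                 offspring_per_generation = as.integer(offspring_per_generation),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 max_iterations = as.integer(max_iterations),
                 patience = as.integer(patience), replacement = replacement),
            class = "ga_config")
}

.scored <- function(ind, model) {
  ind$fitness <- as.numeric(fitness_score(model, encode_features(ind$labels)))
  ind
}

#' Initialize the evolutionary population
#'
#' @param map A [density_map()].
#' @param config A [ga_config()].
#' @param model A fitness scorer (see [fitness_score()]).
#' @param seed Optional RNG seed.
#' @return List of `population_size` scored [individual()]s.
#' @export
init_population <- function(map, config = ga_config(), model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(config$population_size),
         function(i) .scored(random_segmentation(map), model))
}

#' Fitness-weighted round-robin parent selection
#'
#' Samples `parents_per_generation` parents with replacement, probability
#' proportional to fitness (uniform when all fitness values are equal or
#' zero); consecutive parents in the returned list are the round-robin pairs
#' for crossover (1st with 2nd, 3rd with 4th, ...). High-fitness individuals
#' can be parents many times.
#'
#' @param population List of scored [individual()]s.
#' @param config A [ga_config()].
#' @return Ordered list of parents (length `parents_per_generation`).
#' @export
select_parents <- function(population, config = ga_config()) {
  if (length(population) == 0L) stop("empty population", call. = FALSE)
  fit <- vapply(population, function(p) p$fitness, numeric(1))
  if (anyNA(fit)) stop("population has unscored individuals", call. = FALSE)
  w <- if (sum(fit) <= 0 || diff(range(fit)) == 0)
    rep(1, length(fit)) else fit
  idx <- sample.int(length(population), config$parents_per_generation,
                    replace = TRUE, prob = w)
  population[idx]
}

.segment_list <- function(labels) {
  lab <- as.vector(labels$labels)
  fg <- which(lab > 0L)
  split(fg, lab[fg])
}

#' Crossover: offspring by superposition of parental segments
#'
#' Segments from the union of both parents' segment sets are drawn uniformly
#' at random and stamped onto the offspring; a stamped segment claims only
#' voxels that are not yet labelled (first placed wins), and the process
#' stops when every foreground voxel carries a label. Offspring segments are
#' therefore subsets of parental segments; empty residuals are discarded and
#' labels canonicalized.
#'
#' @param a,b [individual()]s segmenting the same foreground.
#' @return An unscored [individual()].
#' @export
crossover <- function(a, b) {
  stopifnot(inherits(a, "evoseg_individual"), inherits(b, "evoseg_individual"))
  la <- a$labels$labels
  lb <- b$labels$labels
  if (!identical(dim(la), dim(lb)) || !identical(la > 0L, lb > 0L))
    stop("parents segment different foregrounds", call. = FALSE)
  segs <- c(.segment_list(a$labels), .segment_list(b$labels))
  off <- integer(length(la))
  remaining <- sum(la > 0L)
  nxt <- 0L
  for (s in sample(length(segs))) {
    vox <- segs[[s]]
    free <- vox[off[vox] == 0L]
    if (length(free)) {
      nxt <- nxt + 1L
      off[free] <- nxt
      remaining <- remaining - length(free)
      if (remaining == 0L) break
    }
  }
  individual(canonicalize_labels(label_map(array(off, dim(la)))))
}

# face-adjacent (6-neighbourhood) label pairs present in a label array
.adjacent_pairs <- function(lab) {
  d <- dim(lab)
  pairs <- NULL
  for (axis in 1:3) {
    n <- d[axis]
    if (n < 2L) next
    idx_lo <- lapply(1:3, function(a) if (a == axis) 1:(n - 1) else
      seq_len(d[a]))
    idx_hi <- lapply(1:3, function(a) if (a == axis) 2:n else seq_len(d[a]))
    u <- lab[idx_lo[[1]], idx_lo[[2]], idx_lo[[3]]]
    v <- lab[idx_hi[[1]], idx_hi[[2]], idx_hi[[3]]]
    sel <- u > 0L & v > 0L & u != v
    if (any(sel)) pairs <- rbind(pairs, unique(cbind(pmin(u[sel], v[sel]),
                                                     pmax(u[sel], v[sel]))))
  }
  if (is.null(pairs)) matrix(integer(), 0, 2) else unique(pairs)
}

#' Merge mutation
#'
#' A uniformly chosen segment is united with a uniformly chosen face-adjacent
#' neighbour under a fresh label, reducing the segment count by exactly one.
#' If no two segments are adjacent the mutation is the identity.
#'
#' @param ind An [individual()].
#' @return An unscored [individual()].
#' @export
mutate_merge <- function(ind) {
  stopifnot(inherits(ind, "evoseg_individual"))
  lab <- ind$labels$labels
  pairs <- .adjacent_pairs(lab)
  if (nrow(pairs) == 0L) return(individual(ind$labels, ind$sigma, ind$steps))
  candidates <- sort(unique(as.vector(pairs)))   # segments with a neighbour
  s <- candidates[sample.int(length(candidates), 1L)]
  nb <- unique(c(pairs[pairs[, 1] == s, 2], pairs[pairs[, 2] == s, 1]))
  other <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L)]
  fresh <- max(lab) + 1L
  lab[lab == s | lab == other] <- fresh
  individual(canonicalize_labels(label_map(lab)))
}

#' Split mutation
#'
#' A uniformly chosen segment `Q` is replaced by its intersection with the
#' regions of a fresh random watershed (random sigma, steps) restricted to
#' `Q`'s voxels. If the restricted watershed leaves `Q` in a single region a
#' new random segmentation is drawn, up to `max_retries` times, after which
#' the mutation is the identity.
#'
#' @param ind An [individual()].
#' @param map The [density_map()] being segmented.
#' @param max_retries Redraws before giving up.
#' @return An unscored [individual()].
#' @export
mutate_split <- function(ind, map, max_retries = 5L) {
  stopifnot(inherits(ind, "evoseg_individual"), inherits(map, "density_map"))
  lab <- ind$labels$labels
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  q <- ids[sample.int(length(ids), 1L)]
  d <- dim(lab)
  mask <- as.vector(lab == q)
  if (sum(mask) < 2L) return(individual(ind$labels, ind$sigma, ind$steps))
  for (r in seq_len(max_retries)) {
    sigma <- runif(1, 1, 4)
    steps <- sample(1:4, 1L)
    w <- watershed_cpp(as.numeric(map$grid), d, mask)
    pieces <- scale_space_group(label_map(array(w, d)), map,
                                watershed_params(sigma, steps))$labels
    np <- length(setdiff(unique(pieces[lab == q]), 0L))
    if (np >= 2L) {
      out <- lab
      out[lab == q] <- max(lab) + pieces[lab == q]
      return(individual(canonicalize_labels(label_map(out))))
    }
  }
  individual(ind$labels, ind$sigma, ind$steps)
}

#' Create one offspring from a parent pair
#'
#' With probability `p_crossover` the offspring is the [crossover()] of the
#' pair, otherwise a direct copy of one uniformly chosen parent; then with
#' probability `p_mutation` one mutation (merge or split, equally likely) is
#' applied. The returned individual carries attributes `crossed` and
#' `mutation` recording which operators fired.
#'
#' @param pair List of two [individual()]s.
#' @param config A [ga_config()].
#' @param map The [density_map()] (needed by the split mutation).
#' @return An unscored [individual()].
#' @export
make_offspring <- function(pair, config = ga_config(), map) {
  crossed <- runif(1) < config$p_crossover
  off <- if (crossed) crossover(pair[[1]], pair[[2]])
         else {
           p <- pair[[sample.int(2L, 1L)]]
           individual(p$labels, p$sigma, p$steps)
         }
  mutation <- "none"
  if (runif(1) < config$p_mutation) {
    mutation <- sample(c("merge", "split"), 1L)
    off <- if (mutation == "merge") mutate_merge(off)
           else mutate_split(off, map)
  }
  attr(off, "crossed") <- crossed
  attr(off, "mutation") <- mutation
  off
}

#' Run the evolutionary segmentation optimizer
#'
#' Iterates select - crossover/mutate - score - replace until `patience`
#' consecutive generations bring no higher fitness or `max_iterations` is
#' reached. `"generational"` replacement builds each new population from the
#' offspring plus fresh random segmentations (the whole population can turn
#' over, which gives the characteristic score fluctuations); `"elitist"`
#' retains the top-fitness individuals and fills the remainder with
#' offspring. The best individual ever seen is archived and returned even if
#' it leaves the population.
#'
#' @param map A [density_map()].
#' @param model A fitness scorer (see [fitness_score()]).
#' @param config A [ga_config()].
#' @param truth Optional ground-truth [label_map()]; when supplied the run
#'   log tracks the matched IoU of the best individual per generation.
#' @param seed Optional RNG seed making the whole run reproducible.
#' @return An `evoseg_run`: list with `best` (the archived best
#'   [individual()]), `log` (one tibble row per generation: `generation`,
#'   `best_score`, `mean_score`, `best_ever`, `matched_iou`,
#'   `n_segments_best`, `crossovers`, `mutations`), `stopping_reason`,
#'   `config` and `seed`.
#' @export
run_evolution <- function(map, model, config = ga_config(), truth = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- lapply(seq_len(config$population_size),
                function(i) .scored(random_segmentation(map), model))
  fit <- vapply(pop, function(p) p$fitness, numeric(1))
  best_ind <- pop[[which.max(fit)]]
  best_fit <- max(fit)
  stall <- 0L
  logs <- vector("list", config$max_iterations)
  reason <- "max_iterations"

  for (gen in seq_len(config$max_iterations)) {
    parents <- select_parents(pop, config)
    n_off <- config$offspring_per_generation
    offspring <- vector("list", n_off)
    crossovers <- 0L
    mutations <- 0L
    for (k in seq_len(n_off)) {
      pi <- ((k - 1L) * 2L) %% config$parents_per_generation + 1L
      off <- make_offspring(parents[pi + 0:1], config, map)
      crossovers <- crossovers + attr(off, "crossed")
      mutations <- mutations + (attr(off, "mutation") != "none")
      offspring[[k]] <- .scored(off, model)
    }

    n_fill <- config$population_size - n_off
    pop <- if (config$replacement == "generational") {
      fill <- lapply(seq_len(max(n_fill, 0L)),
                     function(i) .scored(random_segmentation(map), model))
      c(offspring, fill)[seq_len(config$population_size)]
    } else {
      ord <- order(vapply(pop, function(p) p$fitness, numeric(1)),
                   decreasing = TRUE)
      c(pop[ord[seq_len(max(n_fill, 0L))]], offspring)[
        seq_len(config$population_size)]
    }

    fit <- vapply(pop, function(p) p$fitness, numeric(1))
    gen_best <- max(fit)
    if (gen_best > best_fit) {
      best_fit <- gen_best
      best_ind <- pop[[which.max(fit)]]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }

    logs[[gen]] <- tibble(
      generation = gen, best_score = gen_best, mean_score = mean(fit),
      best_ever = best_fit,
      matched_iou = if (is.null(truth)) NA_real_ else
        matched_iou(best_ind$labels, truth)$value,
      n_segments_best = n_segments(best_ind$labels),
      crossovers = crossovers, mutations = mutations)

    if (stall >= config$patience) {
      reason <- "patience"
      break
    }
  }

  structure(
    list(best = best_ind, log = do.call(rbind, logs[!vapply(logs, is.null,
                                                            TRUE)]),
         stopping_reason = reason, config = config, seed = seed),
    class = "evoseg_run")
}

#' @export
print.evoseg_run <- function(x, ...) {
  cat(sprintf("<evoseg_run> %d generation(s), stopped by %s\n",
              nrow(x$log), x$stopping_reason))
  cat(sprintf("  best fitness %.4f with %d segment(s)\n", x$best$fitness,
              n_segments(x$best$labels)))
  invisible(x)
}

#' @rdname run_evolution
#' @param x An `evoseg_run`.
#' @param ... Unused.
#' @export
tidy.evoseg_run <- function(x, ...) x$log

#' @rdname run_evolution
#' @export
glance.evoseg_run <- function(x, ...) {
  tibble(generations = nrow(x$log), best_fitness = x$best$fitness,
         n_segments_best = n_segments(x$best$labels),
         stopping_reason = x$stopping_reason,
         replacement = x$config$replacement)
}
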