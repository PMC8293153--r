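# Synthetic multi-subunit phantoms.
#
# Real training data for the segmentation-quality classifier comes from EM
# maps paired with deposited atomic structures; that pathway needs downloads.
# The phantom generator stands in for it: each subunit is a union of
# overlapping isotropic Gaussian blobs, subunits are placed in contact so they
# share the fuzzy boundaries that make watershed merge or split them wrongly,
# the whole map is low-pass (resolution) blurred and corrupted with additive
# Gaussian noise, and the exact per-voxel subunit assignment is returned as
# ground truth.

#' Specify a synthetic phantom
#'
#' @param n_subunits Number of protein subunits (>= 1; real assemblies of
#'   interest have at least 2).
#' @param grid_shape Grid dimensions `c(nx, ny, nz)`.
#' @param blobs_per_subunit Range (length 2) of the number of Gaussian blobs
#'   composing one subunit.
#' @param blob_radius Range of blob radii in voxels (the Gaussian sd is half
#'   the radius).
#' @param resolution_sigma Resolution blur width in voxels. Blobs are
#'   Gaussian, so the blur is folded in analytically:
#'   `sd_effective = sqrt((radius/2)^2 + resolution_sigma^2)`.
#' @param noise_sd Additive Gaussian noise sd, relative to the peak pre-noise
#'   density.
#' @param voxel_size Voxel size in Angstrom recorded on the output map.
#' @param seed RNG seed making the phantom fully reproducible.
#' @return A `phantom_spec` object.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(n_subunits = 2, seed = 7))
#' n_segments(ph$truth)
phantom_spec <- function(n_subunits = 2L, grid_shape = c(32L, 32L, 32L),
                         blobs_per_subunit = c(2L, 4L),
                         blob_radius = c(3, 5), resolution_sigma = 1.5,
                         noise_sd = 0.05, voxel_size = 1, seed = 1L) {
  stopifnot(n_subunits >= 1, length(grid_shape) == 3, all(grid_shape >= 4),
            all(blobs_per_subunit >= 1), all(blob_radius > 0),
            resolution_sigma >= 0, noise_sd >= 0)
  structure(
    list(n_subunits = as.integer(n_subunits),
         grid_shape = as.integer(grid_shape),
         blobs_per_subunit = as.integer(range(blobs_per_subunit)),
         blob_radius = as.numeric(range(blob_radius)),
         resolution_sigma = resolution_sigma, noise_sd = noise_sd,
         voxel_size = voxel_size, seed = as.integer(seed)),
    class = "phantom_spec")
}

# separable Gaussian blob field, peak 1 at `center`
.blob_field <- function(d, center, sd) {
  gx <- exp(-0.5 * ((seq_len(d[1]) - center[1]) / sd)^2)
  gy <- exp(-0.5 * ((seq_len(d[2]) - center[2]) / sd)^2)
  gz <- exp(-0.5 * ((seq_len(d[3]) - center[3]) / sd)^2)
  outer(outer(gx, gy), gz)
}

#' Generate a phantom density map with exact ground truth
#'
#' Subunit centers are placed sequentially: each new subunit sits at distance
#' about the sum of effective radii from a randomly chosen existing subunit
#' (1.2 x the sum of nominal radii — the blobs composing a subunit are offset
#' from its center, so each subunit extends beyond its nominal radius), so
#' adjacent subunits share a fuzzy boundary as macromolecular contacts do.
#' The pre-noise density is the sum of all blob fields; the map's contour
#' threshold emulates an author-recommended contour level: 15% of the
#' pre-noise peak, raised to 5 noise standard deviations when the map is
#' noisy, so the envelope stays clear of solvent dust (as recommended
#' contours are chosen to do). Ground truth assigns each
#' pre-noise foreground voxel to the subunit whose blob field is largest
#' there (ties break to the lowest subunit index).
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_pair`: list with `map` ([density_map()]), `truth`
#'   ([label_map()]), `subunit_volumes` (voxel counts per subunit) and the
#'   `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed_(spec$seed, {
    d <- spec$grid_shape
    ns <- spec$n_subunits
    r_sub <- mean(spec$blob_radius)          # effective subunit radius
    margin <- max(2, r_sub / 2 + spec$resolution_sigma)

    centers <- matrix(NA_real_, ns, 3)
    centers[1, ] <- (d + 1) / 2 + runif(3, -1, 1)
    if (ns > 1) {
      for (i in 2:ns) {
        placed <- FALSE
        for (try in 1:200) {
          j <- sample.int(i - 1L, 1L)
          u <- rnorm(3)
          u <- u / sqrt(sum(u^2))
          cand <- centers[j, ] + u * (2 * r_sub * 1.2)
          if (all(cand > margin) && all(cand < d - margin + 1)) {
            centers[i, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("phantom placement failed: grid too small for the requested subunits",
               call. = FALSE)
      }
    }

    fields <- vector("list", ns)
    for (i in seq_len(ns)) {
      nb <- sample(spec$blobs_per_subunit[1]:spec$blobs_per_subunit[2], 1L)
      f <- array(0, d)
      for (b in seq_len(nb)) {
        r <- runif(1, spec$blob_radius[1], spec$blob_radius[2])
        off <- runif(3, -0.4 * r_sub, 0.4 * r_sub)
        sd_eff <- sqrt((r / 2)^2 + spec$resolution_sigma^2)
        f <- f + .blob_field(d, centers[i, ] + off, sd_eff)
      }
      fields[[i]] <- f
    }

    clean <- Reduce(`+`, fields)
    peak <- max(clean)
    threshold <- max(0.15, 5 * spec$noise_sd) * peak

    fg <- clean > threshold
    # argmax over subunit fields; ties -> lowest subunit index
    truth <- array(0L, d)
    if (ns == 1L) {
      truth[fg] <- 1L
    } else {
      best_val <- array(-Inf, d)
      for (i in seq_len(ns)) {
        take <- fg & (fields[[i]] > best_val)
        truth[take] <- i
        best_val <- pmax(best_val, fields[[i]] * fg)
      }
    }

    noisy <- clean + rnorm(length(clean), 0, spec$noise_sd * peak)
    map <- density_map(array(noisy, d), voxel_size = spec$voxel_size,
                       threshold = threshold)
    structure(
      list(map = map, truth = label_map(truth),
           subunit_volumes = as.integer(tabulate(truth[truth > 0L], ns)),
           spec = spec),
      class = "phantom_pair")
  })
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("<phantom_pair> %d subunit(s), %d foreground voxel(s), noise sd %.3g\n",
              x$spec$n_subunits, sum(x$subunit_volumes), x$spec$noise_sd))
  invisible(x)
}

#' Generate a reproducible collection of phantoms
#'
#' The curated real-data collection this mirrors holds 73 annotated maps;
#' `generate_dataset(73)` produces the synthetic analogue.
#'
#' @param n_maps Number of phantoms (>= 1).
#' @param spec_sampler Optional `function(i, seed)` returning the
#'   [phantom_spec()] for map `i`; the default draws 2-5 subunits on a 24^3
#'   grid with the default blob, blur and noise settings.
#' @param seed RNG seed; per-map seeds are derived from it.
#' @return A list of `phantom_pair` objects.
#' @export
generate_dataset <- function(n_maps, spec_sampler = NULL, seed = 1L) {
  stopifnot(n_maps >= 1)
  seeds <- derive_seeds_(seed, n_maps)
  sampler <- spec_sampler %||% function(i, seed) {
    with_seed_(seed, {
      ns <- sample(2:5, 1L)
      phantom_spec(n_subunits = ns, grid_shape = c(24L, 24L, 24L),
                   blob_radius = c(2.5, 4), seed = derive_seeds_(seed, 1L))
    })
  }
  lapply(seq_len(n_maps), function(i) generate_phantom(sampler(i, seeds[i])))
}
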