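# Baseline segmentation: immersion watershed on the density (proteins are the
# "peaks"; each local maximum grows a basin) followed by rounds of scale-space
# grouping, where the density is repeatedly Gaussian-smoothed and basins whose
# seed maxima coalesce in the smoothed field are merged.

#' Watershed / grouping parameters
#'
#' `sigma` is the Gaussian smoothing width applied in each grouping round and
#' `steps` the number of rounds. When drawn at random for the evolutionary
#' optimizer, `sigma` is continuous on \[1, 4\] and `steps` uniform on
#' \{1, 2, 3, 4\}.
#'
#' @param sigma Smoothing width in voxels (> 0).
#' @param steps Number of grouping rounds (>= 0; 0 is the identity).
#' @return A `watershed_params` object.
#' @export
watershed_params <- function(sigma = 2, steps = 2L) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0,
            steps >= 0, steps == round(steps))
  structure(list(sigma = as.numeric(sigma), steps = as.integer(steps)),
            class = "watershed_params")
}

#' Gaussian smoothing of a density grid
#'
#' Separable convolution with a truncated (3 sd) Gaussian kernel and
#' reflected boundaries.
#'
#' @param x A [density_map()] or 3D numeric array.
#' @param sigma Kernel width in voxels.
#' @return Same type as the input.
#' @export
gaussian_smooth <- function(x, sigma) {
  if (inherits(x, "density_map")) {
    x$grid <- gaussian_smooth(x$grid, sigma)
    return(x)
  }
  stopifnot(is.array(x), length(dim(x)) == 3L)
  array(gaussian_smooth_cpp(as.numeric(x), dim(x), sigma), dim(x))
}

#' Immersion watershed segmentation
#'
#' Labels every foreground voxel: voxels are visited in order of decreasing
#' density; a voxel with no labelled 6-neighbour seeds a new basin (it is a
#' local maximum), otherwise it joins the basin of its highest-density
#' labelled neighbour. Deterministic: density ties break by voxel index.
#'
#' @param map A [density_map()] with a threshold set (or estimable).
#' @return A [label_map()] with labels `1..K` covering exactly the foreground.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(n_subunits = 2, noise_sd = 0, seed = 3))
#' n_segments(watershed_segment(ph$map))
watershed_segment <- function(map) {
  stopifnot(inherits(map, "density_map"))
  mask <- foreground_mask(map)
  if (!any(mask))
    stop("empty map: no voxel above the contour threshold", call. = FALSE)
  lab <- watershed_cpp(as.numeric(map$grid), dim(map$grid), as.vector(mask))
  label_map(array(lab, dim(map$grid)))
}

#' Scale-space grouping of watershed regions
#'
#' Performs `params$steps` rounds. Each round smooths the working density
#' with a Gaussian of width `params$sigma` (rounds compound, so the effective
#' scale grows), recomputes basins of the smoothed field on the same
#' foreground, and merges regions whose seed maxima fall into the same
#' smoothed basin. The segment count never increases and background is never
#' relabelled.
#'
#' @param labels A [label_map()] from [watershed_segment()] on `map`.
#' @param map The [density_map()] the labels were derived from.
#' @param params A [watershed_params()].
#' @return A [label_map()] with canonical labels.
#' @export
scale_space_group <- function(labels, map, params) {
  stopifnot(inherits(labels, "label_map"), inherits(map, "density_map"),
            inherits(params, "watershed_params"))
  if (!identical(dim(labels$labels), dim(map$grid)))
    stop("labels and map have different grid shapes", call. = FALSE)
  if (params$steps == 0L) return(labels)

  d <- dim(map$grid)
  lab <- labels$labels
  mask <- as.vector(lab > 0L)
  sm <- as.numeric(map$grid)
  for (round in seq_len(params$steps)) {
    ids <- sort(setdiff(unique(as.vector(lab)), 0L))
    if (length(ids) <= 1L) break
    sm <- gaussian_smooth_cpp(sm, d, params$sigma)
    basins <- watershed_cpp(sm, d, mask)
    # seed of each region: its highest voxel in the current smoothed field
    labv <- as.vector(lab)
    fg <- which(labv > 0L)
    ord <- fg[order(labv[fg], -sm[fg], fg)]
    seed_idx <- ord[!duplicated(labv[ord])]          # one per region id
    group_of <- basins[seed_idx][match(labv[fg], labv[seed_idx])]
    newlab <- integer(length(labv))
    newlab[fg] <- group_of
    lab <- array(newlab, d)
  }
  canonicalize_labels(label_map(lab))
}

#' Random watershed segmentation state
#'
#' Draws `sigma ~ Uniform[1, 4]` and `steps ~ Uniform{1..4}`, runs the
#' watershed and grouping, and wraps the result as one individual of the
#' evolutionary population, carrying its `(sigma, steps)` provenance. Uses
#' the ambient RNG stream (seed it with `set.seed()` for reproducibility).
#'
#' @param map A [density_map()].
#' @return An [individual()].
#' @export
random_segmentation <- function(map) {
  sigma <- runif(1, 1, 4)
  steps <- sample(1:4, 1L)
  ws <- watershed_segment(map)
  grouped <- scale_space_group(ws, map, watershed_params(sigma, steps))
  individual(grouped, sigma = sigma, steps = steps)
}
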