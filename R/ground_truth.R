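# Ground truth from atomic models: when a map has a deposited structure, each
# chain is one subunit and foreground voxels are assigned to the chain of
# their nearest atom (within a cutoff). Plus the dataset curation filters
# (subunit count, resolution window, map/model volume ratio).

#' Read atom coordinates from a PDB or mmCIF file
#'
#' A minimal plain-text reader: PDB `ATOM`/`HETATM` records (fixed columns)
#' or the `_atom_site` loop of an mmCIF file. Only what ground-truth
#' annotation needs is kept: chain identifier and Cartesian coordinates in
#' Angstrom.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif` file.
#' @return A tibble with columns `chain`, `x`, `y`, `z`.
#' @export
read_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE) ||
    any(startsWith(lines, "_atom_site."))
  atoms <- if (is_cif) .read_cif_atoms(lines) else .read_pdb_atoms(lines)
  if (nrow(atoms) == 0L)
    stop(sprintf("'%s': no atom records found", path), call. = FALSE)
  atoms
}

.read_pdb_atoms <- function(lines) {
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  tibble(chain = trimws(substr(rec, 22, 22)),
         x = as.numeric(substr(rec, 31, 38)),
         y = as.numeric(substr(rec, 39, 46)),
         z = as.numeric(substr(rec, 47, 54)))
}

.read_cif_atoms <- function(lines) {
  fields <- grep("^_atom_site\\.", lines)
  if (length(fields) == 0L)
    return(tibble(chain = character(), x = numeric(), y = numeric(),
                  z = numeric()))
  names <- sub("^_atom_site\\.", "", trimws(lines[fields]))
  first_row <- max(fields) + 1L
  rows <- character()
  for (i in first_row:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "loop_") ||
        startsWith(ln, "_")) break
    rows <- c(rows, ln)
  }
  tok <- strsplit(rows, "\\s+")
  get <- function(field, alt = NULL) {
    j <- match(field, names)
    if (is.na(j) && !is.null(alt)) j <- match(alt, names)
    if (is.na(j)) return(rep(NA_character_, length(tok)))
    vapply(tok, `[`, "", j)
  }
  tibble(chain = get("auth_asym_id", "label_asym_id"),
         x = as.numeric(get("Cartn_x")),
         y = as.numeric(get("Cartn_y")),
         z = as.numeric(get("Cartn_z")))
}

#' Annotate a map's foreground from an atomic model
#'
#' Each foreground voxel is assigned the label of the chain containing its
#' nearest atom, by physical-coordinate distance (map origin and voxel size
#' applied). Voxels farther than `cutoff` from every atom stay background.
#' Chains are numbered in sorted order of their identifiers, and a voxel
#' exactly equidistant from two chains goes to the lower chain index.
#'
#' @param map A [density_map()].
#' @param model Atom tibble from [read_structure()] (columns `chain`, `x`,
#'   `y`, `z`).
#' @param cutoff Maximum voxel-to-atom distance in Angstrom.
#' @return A [label_map()]; label `k` is the `k`-th chain in sorted order.
#' @export
annotate_from_model <- function(map, model, cutoff = 5) {
  stopifnot(inherits(map, "density_map"))
  if (is.null(model) || nrow(model) == 0L)
    stop("empty atomic model", call. = FALSE)
  mask <- foreground_mask(map)
  if (!any(mask)) stop("empty map: no foreground to annotate", call. = FALSE)
  d <- dim(map$grid)
  idx <- which(mask)
  ai <- arrayInd(idx, d)
  coords <- sweep(sweep(ai - 1, 2L, map$voxel_size, "*"), 2L, map$origin, "+")
  chains <- sort(unique(model$chain))
  dist <- matrix(Inf, length(idx), length(chains))
  for (ci in seq_along(chains)) {
    at <- as.matrix(model[model$chain == chains[ci], c("x", "y", "z")])
    nn <- FNN::get.knnx(at, coords, k = 1L)
    dist[, ci] <- nn$nn.dist[, 1L]
  }
  best <- apply(dist, 1L, which.min)       # ties -> first (lowest) chain
  best[dist[cbind(seq_along(best), best)] > cutoff] <- 0L
  lab <- array(0L, d)
  lab[idx] <- as.integer(best)
  label_map(lab)
}

#' One candidate entry of an annotated dataset
#'
#' @param id Entry identifier.
#' @param resolution Reported map resolution in Angstrom.
#' @param n_subunits Number of subunits (chains); derived from `model` when
#'   omitted.
#' @param map Optional [density_map()] (needed for the volume-ratio check).
#' @param model Optional atom tibble from [read_structure()].
#' @param cutoff Envelope cutoff for the model-derived volume, in Angstrom.
#' @return A `dataset_entry` with `accepted = NA` until filtered.
#' @export
dataset_entry <- function(id, resolution, n_subunits = NULL, map = NULL,
                          model = NULL, cutoff = 5) {
  if (is.null(n_subunits) && !is.null(model))
    n_subunits <- length(unique(model$chain))
  structure(list(id = id, resolution = as.numeric(resolution),
                 n_subunits = n_subunits, map = map, model = model,
                 cutoff = cutoff, accepted = NA, rejection_reason = ""),
            class = "dataset_entry")
}

#' Apply the dataset curation filters to an entry
#'
#' An entry is accepted when it has at least 2 subunits, its resolution lies
#' in the 4.5-10 Angstrom window, and (when both map and model are present)
#' the map-to-model volume ratio passes [volume_ratio_filter()]. Pure
#' predicate: idempotent, no side effects beyond the `accepted` /
#' `rejection_reason` fields.
#'
#' @param entry A [dataset_entry()].
#' @return The entry with `accepted` and `rejection_reason` set.
#' @export
apply_filters <- function(entry) {
  stopifnot(inherits(entry, "dataset_entry"))
  reject <- function(why) {
    entry$accepted <- FALSE
    entry$rejection_reason <- why
    entry
  }
  if (is.null(entry$n_subunits) || is.na(entry$n_subunits))
    stop("entry is missing the subunit count", call. = FALSE)
  if (is.null(entry$resolution) || is.na(entry$resolution))
    stop("entry is missing the resolution", call. = FALSE)
  if (entry$n_subunits < 2L)
    return(reject("fewer than 2 subunits"))
  if (entry$resolution < 4.5 || entry$resolution > 10)
    return(reject("resolution outside 4.5-10 A"))
  if (!is.null(entry$map) && !is.null(entry$model)) {
    map_vol <- sum(foreground_mask(entry$map))
    ann <- annotate_from_model(
      density_map(entry$map$grid, entry$map$voxel_size, entry$map$origin,
                  threshold = min(entry$map$grid) - 1),   # whole grid
      entry$model, cutoff = entry$cutoff)
    model_vol <- sum(ann$labels > 0L)
    if (!volume_ratio_filter(map_vol, model_vol))
      return(reject("map/model volume ratio outside [0.8, 1.2]"))
  }
  entry$accepted <- TRUE
  entry$rejection_reason <- ""
  entry
}

#' @export
print.dataset_entry <- function(x, ...) {
  status <- if (is.na(x$accepted)) "unfiltered"
            else if (x$accepted) "accepted"
            else sprintf("rejected (%s)", x$rejection_reason)
  cat(sprintf("<dataset_entry> %s: %.1f A, %s subunit(s), %s\n", x$id,
              x$resolution, x$n_subunits %||% "?", status))
  invisible(x)
}
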