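# Evaluation of a predicted segmentation against ground truth. The central
# quantity is the matched IoU: since segment identifiers are arbitrary, the
# prediction's labels are put in the one-to-one correspondence with ground
# truth that maximizes total intersection-over-union before averaging.

# contingency of positive labels over the union foreground
.overlap_tables <- function(pred, truth) {
  p <- as.vector(pred$labels)
  t <- as.vector(truth$labels)
  if (length(p) != length(t))
    stop("prediction and ground truth have different grid shapes",
         call. = FALSE)
  keep <- p > 0L | t > 0L
  p <- p[keep]
  t <- t[keep]
  pl <- sort(setdiff(unique(p), 0L))
  tl <- sort(setdiff(unique(t), 0L))
  inter <- matrix(0, length(pl), length(tl), dimnames = list(pl, tl))
  both <- p > 0L & t > 0L
  if (any(both)) {
    tab <- table(factor(p[both], levels = pl), factor(t[both], levels = tl))
    inter[] <- as.numeric(tab)
  }
  list(inter = inter,
       psize = tabulate(p, max(c(p, 1L)))[pl],
       tsize = tabulate(t, max(c(t, 1L)))[tl],
       pl = pl, tl = tl)
}

.iou_matrix <- function(ov) {
  if (length(ov$pl) == 0L || length(ov$tl) == 0L)
    return(matrix(0, length(ov$pl), length(ov$tl)))
  un <- outer(ov$psize, ov$tsize, `+`) - ov$inter
  ov$inter / un
}

#' Permutation-matched IoU between a prediction and ground truth
#'
#' Builds the pairwise IoU matrix between predicted and ground-truth
#' segments and finds the one-to-one label correspondence maximizing total
#' IoU (optimal linear assignment, equivalent to searching all label
#' permutations). Two aggregation modes:
#' * `"all"` — mean IoU over `max(p, t)` slots, unmatched slots contributing
#'   0, so both over- and under-segmentation are penalized;
#' * `"matched_only"` — mean IoU over matched pairs only (pairs with
#'   positive overlap), ignoring surplus segments.
#'
#' @param pred,truth [label_map()]s on the same grid.
#' @param mode `"all"` or `"matched_only"`.
#' @return A list with `value` (numeric in \[0, 1\]) and `matching`, a tibble
#'   of matched `(pred_label, truth_label, iou)` pairs.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 5))
#' matched_iou(ph$truth, ph$truth)$value  # identity: 1
matched_iou <- function(pred, truth, mode = c("all", "matched_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pred, "label_map"), inherits(truth, "label_map"))
  ov <- .overlap_tables(pred, truth)
  p <- length(ov$pl)
  t <- length(ov$tl)
  empty <- tibble(pred_label = integer(), truth_label = integer(),
                  iou = numeric())
  if (p == 0L || t == 0L)
    return(list(value = 0, matching = empty))
  iou <- .iou_matrix(ov)
  n <- max(p, t)
  sq <- matrix(0, n, n)
  sq[seq_len(p), seq_len(t)] <- iou
  sol <- as.integer(clue::solve_LSAP(sq, maximum = TRUE))
  rows <- seq_len(p)
  cols <- sol[rows]
  ok <- cols <= t & iou[cbind(rows, pmin(cols, t))] > 0
  matching <- tibble(pred_label = ov$pl[rows[ok]],
                     truth_label = ov$tl[cols[ok]],
                     iou = iou[cbind(rows[ok], cols[ok])])
  total <- sum(matching$iou)
  value <- if (mode == "all") total / n
           else if (nrow(matching) > 0L) total / nrow(matching) else 0
  list(value = value, matching = matching)
}

#' Homogeneity of a segmentation
#'
#' Voxel-level precision: true positives are the voxels of matched predicted
#' segments that lie inside their matched ground-truth segment; every other
#' voxel of a predicted segment (including all voxels of unmatched segments)
#' is a false positive. `H = TP / (TP + FP)`.
#'
#' @inheritParams matched_iou
#' @param matching Optional matching tibble from [matched_iou()]; recomputed
#'   if missing.
#' @return Numeric in \[0, 1\].
#' @export
homogeneity <- function(pred, truth, matching = NULL) {
  stopifnot(inherits(pred, "label_map"), inherits(truth, "label_map"))
  if (sum(pred$labels > 0L) == 0L)
    stop("prediction has no foreground voxels", call. = FALSE)
  if (is.null(matching)) matching <- matched_iou(pred, truth)$matching
  tp <- 0
  for (i in seq_len(nrow(matching))) {
    tp <- tp + sum(pred$labels == matching$pred_label[i] &
                   truth$labels == matching$truth_label[i])
  }
  tp / sum(pred$labels > 0L)
}

#' Proportion of predicted segments per ground-truth subunit
#'
#' For each ground-truth segment `i`, `s_i` counts the distinct predicted
#' segments with non-zero voxel overlap; `P` is the mean of `s_i` over the
#' `N` ground-truth segments. 1 is ideal; larger values indicate
#' over-segmentation.
#'
#' @inheritParams matched_iou
#' @return Numeric >= 0.
#' @export
proportion_segments <- function(pred, truth) {
  stopifnot(inherits(pred, "label_map"), inherits(truth, "label_map"))
  ov <- .overlap_tables(pred, truth)
  if (length(ov$tl) == 0L)
    stop("ground truth has no segments", call. = FALSE)
  s <- colSums(ov$inter > 0)
  mean(s)
}

#' Consistency of a segmentation
#'
#' The per-subunit split count `s_i` (as in [proportion_segments()])
#' summarized on one designated subunit:
#' * `"largest_volume"` (default) — `s_i` of the ground-truth segment with
#'   the most voxels;
#' * `"max_si"` — the maximum `s_i` over all subunits.
#'
#' @inheritParams matched_iou
#' @param variant Which subunit to report.
#' @return Integer >= 0.
#' @export
consistency <- function(pred, truth, variant = c("largest_volume", "max_si")) {
  variant <- match.arg(variant)
  stopifnot(inherits(pred, "label_map"), inherits(truth, "label_map"))
  ov <- .overlap_tables(pred, truth)
  if (length(ov$tl) == 0L)
    stop("ground truth has no segments", call. = FALSE)
  s <- colSums(ov$inter > 0)
  if (variant == "max_si") as.integer(max(s))
  else as.integer(s[which.max(ov$tsize)])
}

#' Map-to-model volume ratio filter
#'
#' Dataset curation check: a map is kept only when the foreground volume at
#' its contour threshold is proportional to the volume implied by its atomic
#' structure, i.e. the ratio lies in \[0.8, 1.2\] (inclusive).
#'
#' @param map_volume Foreground voxel count of the map at threshold.
#' @param model_volume Voxel count of the structure-derived envelope.
#' @return `TRUE` to keep, `FALSE` to reject.
#' @export
volume_ratio_filter <- function(map_volume, model_volume) {
  if (map_volume <= 0 || model_volume <= 0)
    stop("volumes must be positive", call. = FALSE)
  ratio <- map_volume / model_volume
  ratio >= 0.8 && ratio <= 1.2
}

#' Full evaluation of a predicted segmentation
#'
#' @inheritParams matched_iou
#' @return A `metrics_report`: matched IoU in both modes, homogeneity,
#'   proportion, consistency (both variants), segment counts and the
#'   matching table.
#' @export
evaluate_segmentation <- function(pred, truth) {
  m_all <- matched_iou(pred, truth, "all")
  m_matched <- matched_iou(pred, truth, "matched_only")
  structure(
    list(matched_iou_all = m_all$value,
         matched_iou_matched_only = m_matched$value,
         homogeneity = homogeneity(pred, truth, m_all$matching),
         proportion = proportion_segments(pred, truth),
         consistency = consistency(pred, truth, "largest_volume"),
         consistency_max = consistency(pred, truth, "max_si"),
         n_predicted = n_segments(pred),
         n_truth = n_segments(truth),
         matching = m_all$matching),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  matched IoU (all slots)    %.4f\n", x$matched_iou_all))
  cat(sprintf("  matched IoU (matched only) %.4f\n",
              x$matched_iou_matched_only))
  cat(sprintf("  homogeneity H              %.4f\n", x$homogeneity))
  cat(sprintf("  proportion P               %.4f\n", x$proportion))
  cat(sprintf("  consistency C (largest)    %d   (max s_i: %d)\n",
              x$consistency, x$consistency_max))
  cat(sprintf("  segments: %d predicted vs %d ground truth\n",
              x$n_predicted, x$n_truth))
  invisible(x)
}

#' @rdname evaluate_segmentation
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble(matched_iou_all = x$matched_iou_all,
         matched_iou_matched_only = x$matched_iou_matched_only,
         homogeneity = x$homogeneity,
         proportion = x$proportion,
         consistency = x$consistency,
         consistency_max = x$consistency_max,
         n_predicted = x$n_predicted,
         n_truth = x$n_truth)
}
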