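# Evaluation metrics: pixel-level confusion counts, Dice / sensitivity /
# specificity, connected-component labelling, the aggregated Jaccard index
# (AJI), contour-based cell counting and per-patch report aggregation.

#' Pixel confusion counts between two binary masks
#'
#' @param gt,pred binary masks (`{0, 1}` or logical) of identical shape.
#' @return a list of class `confusion_counts` with integer fields `tp`,
#'   `fp`, `fn`, `tn`; their sum equals the pixel count.
#' @export
confusion_counts <- function(gt, pred) {
  check_same_shape(gt, pred)
  g <- as.logical(gt); p <- as.logical(pred)
  structure(list(tp = sum(g & p), fp = sum(!g & p),
                 fn = sum(g & !p), tn = sum(!g & !p)),
            class = "confusion_counts")
}

#' Pixel-level segmentation metrics
#'
#' Dice `2TP/(2TP+FP+FN)`, sensitivity `TP/(TP+FN)` and specificity
#' `TN/(TN+FP)`. Empty denominators (a class absent from both masks) are
#' scored as perfect agreement (1).
#'
#' @param counts a `confusion_counts` object (or list with tp/fp/fn/tn).
#' @return named numeric vector `(dice, sensitivity, specificity)`.
#' @export
pixel_metrics <- function(counts) {
  safe <- function(num, den) if (den == 0) 1 else num / den
  c(dice = safe(2 * counts$tp, 2 * counts$tp + counts$fp + counts$fn),
    sensitivity = safe(counts$tp, counts$tp + counts$fn),
    specificity = safe(counts$tn, counts$tn + counts$fp))
}

#' Label connected foreground components
#'
#' Each maximal connected foreground region receives a positive integer
#' label; labels are consecutive from 1 in raster order (row by row) of the
#' component's first pixel.
#'
#' @param mask binary matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of instance labels (0 = background).
#' @export
connected_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  m <- mask
  if (is.null(dim(m)) || length(dim(m)) != 2L)
    stop("mask must be a matrix")
  storage.mode(m) <- "integer"
  cc_label_cpp(m, as.integer(connectivity))
}

# overlap (intersection) matrix between two instance maps, plus areas
instance_overlaps <- function(gt, pred) {
  mg <- max(gt); mp <- max(pred)
  ov <- matrix(0, mg, mp)
  if (mg > 0 && mp > 0) {
    both <- gt > 0 & pred > 0
    if (any(both)) {
      tab <- table(factor(gt[both], levels = seq_len(mg)),
                   factor(pred[both], levels = seq_len(mp)))
      ov <- matrix(as.numeric(tab), mg, mp)
    }
  }
  list(ov = ov,
       gt_area = tabulate(gt[gt > 0], nbins = mg),
       pred_area = tabulate(pred[pred > 0], nbins = mp))
}

#' Aggregated Jaccard index
#'
#' For every ground-truth instance the predicted component maximizing the
#' pairwise Jaccard index is selected (ties go to the lower label; a
#' predicted component may be selected by several ground-truth instances).
#' Intersections and unions of the matched pairs are accumulated, and all
#' pixels of predicted components never selected by any ground-truth
#' instance are added to the denominator. Returns 1 when both maps are
#' empty and 0 when the ground truth is non-empty but the prediction is.
#'
#' @param gt,pred instance label maps (non-negative integer matrices, 0 =
#'   background) of identical shape; binary masks are labelled first with
#'   [connected_components()].
#' @param connectivity connectivity used when labelling a binary input.
#' @return the AJI, a real number in `[0, 1]`.
#' @export
aggregated_jaccard <- function(gt, pred, connectivity = 8L) {
  check_same_shape(gt, pred)
  gt <- as_instances(gt, connectivity)
  pred <- as_instances(pred, connectivity)
  mg <- max(gt); mp <- max(pred)
  if (mg == 0L && mp == 0L) return(1)
  if (mg == 0L) return(0)
  if (mp == 0L) return(0)
  o <- instance_overlaps(gt, pred)
  used <- logical(mp)
  inter_sum <- 0
  union_sum <- 0
  for (i in seq_len(mg)) {
    inter <- o$ov[i, ]
    uni <- o$gt_area[i] + o$pred_area - inter
    jac <- inter / uni
    j <- which.max(jac)           # ties: lowest label
    if (jac[j] > 0) {
      used[j] <- TRUE
      inter_sum <- inter_sum + inter[j]
      union_sum <- union_sum + uni[j]
    } else {
      union_sum <- union_sum + o$gt_area[i]   # unmatched gt: its own pixels
    }
  }
  union_sum <- union_sum + sum(o$pred_area[!used])
  inter_sum / union_sum
}

as_instances <- function(x, connectivity) {
  storage.mode(x) <- "integer"
  if (max(x) <= 1L) return(connected_components(x, connectivity))
  x
}

#' Count cells in a binary mask
#'
#' Labels connected components and counts those whose pixel area reaches
#' `min_area`, discarding specks.
#'
#' @param mask binary matrix.
#' @param min_area minimum component area in pixels (default 10).
#' @param connectivity 4 or 8.
#' @return integer cell count.
#' @export
count_cells <- function(mask, min_area = 10L, connectivity = 8L) {
  lab <- connected_components(mask, connectivity)
  if (max(lab) == 0L) return(0L)
  sum(tabulate(lab[lab > 0], nbins = max(lab)) >= min_area)
}

#' Evaluate a list of ground-truth / prediction pairs
#'
#' Computes per-patch Dice, AJI, sensitivity, specificity and cell counts,
#' together with mean and sample standard deviation aggregates and summed
#' cell totals.
#'
#' @param pairs non-empty list; each element a list with `gt` (binary mask
#'   or instance map), `pred` (binary mask) and optionally `id`.
#' @param min_area minimum component area for cell counting.
#' @return an object of class `metrics_report`: list with `per_patch`
#'   (data.frame), `aggregate` (mean/sd per metric) and `totals`.
#' @export
evaluate_pairs <- function(pairs, min_area = 10L) {
  if (length(pairs) == 0L) stop("empty evaluation list")
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    gt <- pr$gt; pred <- pr$pred
    gt_bin <- (gt > 0) * 1L
    pm <- pixel_metrics(confusion_counts(gt_bin, pred))
    data.frame(patch_id = if (!is.null(pr$id)) pr$id else i,
               dice = pm[["dice"]], aji = aggregated_jaccard(gt, pred),
               sensitivity = pm[["sensitivity"]],
               specificity = pm[["specificity"]],
               gt_cell_count = count_cells(gt_bin, min_area),
               pred_cell_count = count_cells(pred, min_area))
  })
  per_patch <- do.call(rbind, rows)
  metric_cols <- c("dice", "aji", "sensitivity", "specificity")
  aggregate <- data.frame(
    metric = metric_cols,
    mean = vapply(per_patch[metric_cols], mean, numeric(1)),
    sd = vapply(per_patch[metric_cols], function(v)
      if (length(v) > 1L) stats::sd(v) else 0, numeric(1)),
    row.names = NULL)
  structure(list(per_patch = per_patch, aggregate = aggregate,
                 totals = c(gt_cells = sum(per_patch$gt_cell_count),
                            pred_cells = sum(per_patch$pred_cell_count))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation metrics over", nrow(x$per_patch), "patches\n")
  for (i in seq_len(nrow(x$aggregate)))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", x$aggregate$metric[i],
                x$aggregate$mean[i], x$aggregate$sd[i]))
  cat(sprintf("  cells: %d ground truth, %d predicted\n",
              x$totals[["gt_cells"]], x$totals[["pred_cells"]]))
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Per-patch rows go to CSV; the aggregates and totals to JSON.
#'
#' @param report a `metrics_report`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, the report.
#' @export
write_metrics_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$per_patch, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(aggregate = report$aggregate,
                              totals = as.list(report$totals)),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
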