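## Segmentation and classification metrics.

as_pixel_sets <- function(x) {
  # accept a label_mask, a candidates tibble (pixel_set list-column), the
  # output of project_mask_to_biosensor(), or a named list of pixel matrices
  if (inherits(x, "label_mask")) {
    labs <- sort(setdiff(unique(as.vector(x$labels)), 0L))
    return(stats::setNames(lapply(labs, function(k) {
      px <- which(x$labels == k, arr.ind = TRUE)
      colnames(px) <- c("row", "col")
      px
    }), as.character(labs)))
  }
  if (is.data.frame(x) && "pixel_set" %in% names(x)) {
    return(stats::setNames(x$pixel_set, as.character(x$cell_id)))
  }
  if (is.list(x) && !is.null(x$pixel_sets)) return(x$pixel_sets)
  stopifnot(is.list(x))
  x
}

pixel_key <- function(px) paste(px[, 1], px[, 2])

#' Match predicted cells to ground-truth cells
#'
#' Greedy one-to-one matching by descending pixel intersection; a truth
#' cell counts as detected when its match's intersection-over-union reaches
#' `min_overlap`. Both arguments may be `label_mask` objects, candidates
#' tibbles, or named lists of `(row, col)` pixel matrices — all on the same
#' plane.
#'
#' @param predicted,truth segmentations to compare.
#' @param min_overlap IoU acceptance threshold (default 0.3).
#' @return a `match_table` tibble: one row per truth cell with
#'   `truth_id`, `pred_id` (NA if unmatched), `intersection`, `union`,
#'   `iou`, `dice`, `detected`.
#' @export
match_cells <- function(predicted, truth, min_overlap = 0.3) {
  pred <- as_pixel_sets(predicted)
  tru <- as_pixel_sets(truth)
  if (length(tru) == 0) abort("no truth cells to match against")
  pred_keys <- lapply(pred, pixel_key)
  tru_keys <- lapply(tru, pixel_key)

  cand <- list()
  for (ti in seq_along(tru)) {
    for (pi in seq_along(pred)) {
      inter <- length(intersect(tru_keys[[ti]], pred_keys[[pi]]))
      if (inter > 0) {
        cand[[length(cand) + 1L]] <- c(ti = ti, pi = pi, inter = inter)
      }
    }
  }
  matched_t <- integer(0); matched_p <- integer(0)
  assign_t <- rep(NA_integer_, length(tru))
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(-cm[, "inter"], cm[, "ti"], cm[, "pi"]), , drop = FALSE]
    for (r in seq_len(nrow(cm))) {
      ti <- cm[r, "ti"]; pi <- cm[r, "pi"]
      if (ti %in% matched_t || pi %in% matched_p) next
      matched_t <- c(matched_t, ti); matched_p <- c(matched_p, pi)
      assign_t[ti] <- pi
    }
  }
  rows <- lapply(seq_along(tru), function(ti) {
    pi <- assign_t[ti]
    if (is.na(pi)) {
      return(tibble(truth_id = names(tru)[ti], pred_id = NA_character_,
                    intersection = 0L, union = nrow(tru[[ti]]),
                    iou = 0, dice = 0, detected = FALSE))
    }
    inter <- length(intersect(tru_keys[[ti]], pred_keys[[pi]]))
    uni <- length(union(tru_keys[[ti]], pred_keys[[pi]]))
    iou <- inter / uni
    tibble(truth_id = names(tru)[ti], pred_id = names(pred)[pi],
           intersection = inter, union = uni, iou = iou,
           dice = 2 * inter / (nrow(tru[[ti]]) + nrow(pred[[pi]])),
           detected = iou >= min_overlap)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("match_table", class(out))
  out
}

#' Detection error
#'
#' Fraction of ground-truth cells without an accepted match (the "lost
#' cell" ratio); 0 is perfect.
#'
#' @param matches a [match_cells()] table.
#' @return scalar in `[0, 1]`.
#' @export
detection_error <- function(matches) {
  if (nrow(matches) == 0) abort("empty match table")
  mean(!matches$detected)
}

#' Dice dissimilarity over matched cells
#'
#' Per matched pair, Dice = `2|A n B| / (|A| + |B|)`; the reported DS is
#' `1 - mean(Dice)` so that, like the detection error, lower is better.
#' `DS_m` is this quantity on the microscope plane, `DS_b` on the biosensor
#' plane. Both the dissimilarity (`ds`) and the mean similarity
#' (`mean_dice`) are returned so either convention is recoverable.
#'
#' @param matches a [match_cells()] table.
#' @param detected_only restrict to accepted matches (default TRUE).
#' @return a list with `ds`, `mean_dice`, `n_pairs`.
#' @export
dice_scores <- function(matches, detected_only = TRUE) {
  m <- if (detected_only) matches[matches$detected, ] else matches[!is.na(matches$pred_id), ]
  if (nrow(m) == 0) abort("no matched pairs to score")
  list(ds = 1 - mean(m$dice), mean_dice = mean(m$dice), n_pairs = nrow(m))
}

#' Full segmentation evaluation
#'
#' @param predicted,truth segmentations on one plane (see [match_cells()]).
#' @param min_overlap IoU acceptance threshold.
#' @return a list of class `segmentation_eval`: `DE`, `DS`, `mean_dice`,
#'   `matches`.
#' @export
evaluate_segmentation <- function(predicted, truth, min_overlap = 0.3) {
  m <- match_cells(predicted, truth, min_overlap)
  ds <- if (any(m$detected)) dice_scores(m) else list(ds = NA_real_, mean_dice = NA_real_,
                                                      n_pairs = 0L)
  structure(list(DE = detection_error(m), DS = ds$ds, mean_dice = ds$mean_dice,
                 matches = m),
            class = "segmentation_eval")
}

#' @export
print.segmentation_eval <- function(x, ...) {
  cat(sprintf("<segmentation_eval> DE = %.3f, DS = %.3f over %d truth cells\n",
              x$DE, x$DS, nrow(x$matches)))
  invisible(x)
}

## ---- classification metrics -------------------------------------------

# rank-based one-vs-rest AUC (equals the Mann-Whitney statistic)
binary_auc <- function(score, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# average precision: step-wise integral of precision over recall, computed
# at every distinct score threshold (descending)
binary_average_precision <- function(score, positive) {
  n_pos <- sum(positive)
  if (n_pos == 0) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  pos <- positive[ord]; sc <- score[ord]
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  keep <- c(diff(sc) != 0, TRUE)  # evaluate at the last index of each tie group
  tp <- tp[keep]; fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Classification report
#'
#' Computes accuracy, macro F1, macro one-vs-rest AUC and macro average
#' precision (AUC-PR) from class probability scores, plus a row-normalized
#' confusion matrix and per-class precision-recall curves. Classes absent
#' from the truth are skipped in the macro averages with a warning.
#'
#' @param probabilities matrix or data frame of per-class scores, columns
#'   named by class (e.g. from [predict_proba()]; a `.pred_class` column is
#'   ignored); rows sum to 1.
#' @param truth character vector of true labels.
#' @param weighted also compute support-weighted F1/AUC/AUC-PR variants.
#' @return an object of class `classification_report`: `accuracy`, `f1`,
#'   `auc`, `auc_pr`, optional weighted variants, `per_class` tibble,
#'   `confusion` (row-normalized matrix), `pr_curves` tibble.
#' @export
classification_report <- function(probabilities, truth, weighted = TRUE) {
  probs <- as.data.frame(probabilities)
  probs$.pred_class <- NULL
  classes <- colnames(probs)
  if (!all(truth %in% classes)) abort("`truth` contains labels with no probability column")
  pm <- as.matrix(probs)
  pred <- classes[apply(pm, 1, which.max)]
  accuracy <- mean(pred == truth)

  per_class <- lapply(classes, function(cl) {
    pos <- truth == cl
    if (!any(pos)) {
      warn(sprintf("class '%s' absent from truth; skipped in macro averages", cl))
      return(tibble(class = cl, support = 0L, precision = NA_real_,
                    recall = NA_real_, f1 = NA_real_, auc = NA_real_,
                    auc_pr = NA_real_))
    }
    tp <- sum(pred == cl & pos)
    fp <- sum(pred == cl & !pos)
    fn <- sum(pred != cl & pos)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- tp / (tp + fn)
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    tibble(class = cl, support = sum(pos), precision = precision,
           recall = recall, f1 = f1,
           auc = binary_auc(pm[, cl], pos),
           auc_pr = binary_average_precision(pm[, cl], pos))
  })
  per_class <- dplyr::bind_rows(per_class)
  present <- per_class$support > 0

  conf <- matrix(0, length(classes), length(classes),
                 dimnames = list(truth = classes, predicted = classes))
  for (i in seq_along(truth)) conf[truth[i], pred[i]] <- conf[truth[i], pred[i]] + 1
  rs <- rowSums(conf)
  conf_norm <- conf / ifelse(rs == 0, 1, rs)

  pr_curves <- dplyr::bind_rows(lapply(classes[present], function(cl) {
    pos <- truth == cl
    ord <- order(pm[, cl], decreasing = TRUE)
    tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
    tibble(class = cl, threshold = pm[ord, cl],
           precision = tp / (tp + fp), recall = tp / sum(pos))
  }))

  wts <- per_class$support[present] / sum(per_class$support[present])
  structure(
    list(accuracy = accuracy,
         f1 = mean(per_class$f1[present]),
         auc = mean(per_class$auc[present]),
         auc_pr = mean(per_class$auc_pr[present]),
         f1_weighted = if (weighted) sum(per_class$f1[present] * wts) else NULL,
         auc_weighted = if (weighted) sum(per_class$auc[present] * wts) else NULL,
         auc_pr_weighted = if (weighted) sum(per_class$auc_pr[present] * wts) else NULL,
         per_class = per_class, confusion = conf_norm, confusion_counts = conf,
         pr_curves = pr_curves, truth = truth, predicted = pred),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> accuracy %.3f, F1 %.3f, AUC %.3f, AUC-PR %.3f (macro)\n",
    x$accuracy, x$f1, x$auc, x$auc_pr))
  invisible(x)
}
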