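## broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a training history
#'
#' @param x an `nn_fit`.
#' @param ... unused.
#' @return the per-epoch history tibble.
#' @export
tidy.nn_fit <- function(x, ...) x$history

#' One-row fit summary
#'
#' @param x an `nn_fit`.
#' @param ... unused.
#' @return tibble with architecture, epochs, best epoch and best-epoch
#'   validation metrics.
#' @export
glance.nn_fit <- function(x, ...) {
  b <- x$history[x$best_epoch, ]
  tibble(architecture = x$model$config$architecture,
         n_classes = x$model$config$n_classes,
         epochs = nrow(x$history), best_epoch = x$best_epoch,
         val_loss = b$val_loss, val_accuracy = b$val_accuracy)
}

#' Per-class metric table
#'
#' @param x a `classification_report`.
#' @param ... unused.
#' @return the per-class precision/recall/F1/AUC/AUC-PR tibble.
#' @export
tidy.classification_report <- function(x, ...) x$per_class

#' One-row macro metric summary
#'
#' @param x a `classification_report`.
#' @param ... unused.
#' @export
glance.classification_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, f1 = x$f1, auc = x$auc, auc_pr = x$auc_pr,
         f1_weighted = x$f1_weighted %||% NA_real_,
         auc_weighted = x$auc_weighted %||% NA_real_,
         auc_pr_weighted = x$auc_pr_weighted %||% NA_real_,
         n = length(x$truth))
}

#' Per-truth-cell match table
#'
#' @param x a `segmentation_eval`.
#' @param ... unused.
#' @export
tidy.segmentation_eval <- function(x, ...) x$matches

#' One-row segmentation summary
#'
#' @param x a `segmentation_eval`.
#' @param ... unused.
#' @export
glance.segmentation_eval <- function(x, ...) {
  tibble(DE = x$DE, DS = x$DS, mean_dice = x$mean_dice,
         n_truth = nrow(x$matches), n_detected = sum(x$matches$detected))
}

#' Per-fold cross-validation metrics
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' Cross-validation summary (mean and sd per metric)
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @export
glance.cv_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  wide
}
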