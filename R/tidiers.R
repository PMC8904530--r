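# broom-style accessors and ggplot2 diagnostics for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-member cross-validation table of a baseline pool
#'
#' @param x A `baseline_pool`.
#' @param ... Unused.
#' @return Tibble with one row per member: `member`, `algorithm`,
#'   `descriptor`, the chosen hyperparameters (list column) and the pooled
#'   cross-validated `acc`, `sn`, `sp`, `mcc`, `auc`.
#' @export
tidy.baseline_pool <- function(x, ...) {
  purrr::map_dfr(names(x$members), function(m) {
    b <- x$members[[m]]
    dplyr::bind_cols(
      tibble::tibble(member = m, algorithm = b$spec$algorithm,
                     descriptor = b$spec$descriptor,
                     params = list(b$chosen_params)),
      b$cv_metrics
    )
  })
}

#' @rdname tidy.baseline_pool
#' @export
glance.baseline_pool <- function(x, ...) {
  tab <- tidy(x)
  best <- tab[which.max(tab$mcc), ]
  tibble::tibble(n_members = length(x$members),
                 n_descriptors = length(x$descriptors),
                 n_algorithms = length(x$algorithms),
                 best_member = best$member, best_mcc = best$mcc)
}

#' Tidy the subset-sweep curve of a selection result
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return Tibble of per-k pooled cross-validated metrics.
#' @export
tidy.selection_result <- function(x, ...) {
  x$per_k[c("k", "acc", "sn", "sp", "mcc", "auc")]
}

#' @rdname tidy.selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(kind = x$kind, chosen_k = x$chosen_k,
                 n_columns = length(x$ranking),
                 best_mcc = max(x$per_k$mcc))
}

#' Tidy the selected meta-features of a stacked model
#'
#' @param x A `scorpion_model`.
#' @param ... Unused.
#' @return Tibble with `rank` and the selected meta-feature `column` names.
#' @export
tidy.scorpion_model <- function(x, ...) {
  tibble::tibble(rank = seq_len(x$selection$chosen_k),
                 column = x$selection$chosen_columns)
}

#' @rdname tidy.scorpion_model
#' @export
glance.scorpion_model <- function(x, ...) {
  tibble::tibble(kind = x$selection$kind, chosen_k = x$selection$chosen_k,
                 n_baselines = length(x$pool$members),
                 threshold = x$threshold)
}

#' Plot the subset-sweep MCC curve
#'
#' @param object A `selection_result`.
#' @param ... Unused.
#' @return A ggplot: pooled cross-validated MCC against subset size, the
#'   chosen size highlighted.
#' @export
autoplot.selection_result <- function(object, ...) {
  dat <- tidy(object)
  chosen <- dat[dat$k == object$chosen_k, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$k, y = .data$mcc)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = chosen, colour = "red", size = 3) +
    ggplot2::labs(x = "top-k meta-features", y = "cross-validated MCC",
                  title = paste0("Subset sweep (", object$kind,
                                 "), chosen k = ", object$chosen_k)) +
    ggplot2::theme_minimal()
}

#' Plot per-member cross-validated MCC of a baseline pool
#'
#' @param object A `baseline_pool`.
#' @param top Show only the `top` best members (default 30).
#' @param ... Unused.
#' @return A ggplot dot chart of member MCCs coloured by descriptor.
#' @export
autoplot.baseline_pool <- function(object, top = 30, ...) {
  tab <- tidy(object)
  tab <- tab[order(-tab$mcc), ][seq_len(min(top, nrow(tab))), ]
  tab$member <- factor(tab$member, levels = rev(tab$member))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mcc, y = .data$member,
                                    colour = .data$descriptor)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "cross-validated MCC", y = NULL,
                  title = "Baseline models") +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param labels 0/1 labels.
#' @param scores Probability scores.
#' @return A ggplot of the ROC curve with its rank-based AUC in the title.
#' @export
plot_roc <- function(labels, scores) {
  pts <- roc_points(labels, scores)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)",
                                  auc_score(labels, scores))) +
    ggplot2::theme_minimal()
}
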