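#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-epoch training history of a fit
#'
#' @param x A `bs_fit`.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `train_loss`, `train_accuracy`,
#'   `val_accuracy`.
#' @export
tidy.bs_fit <- function(x, ...) {
  tibble::as_tibble(x$history)
}

#' One-row summary of a fit
#'
#' @param x A `bs_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `family`, `n_params`, `epochs`,
#'   `final_train_accuracy`, `best_val_accuracy`, `seed`.
#' @export
glance.bs_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    family = x$model$family,
    n_params = n_model_params(x$model),
    epochs = nrow(h),
    final_train_accuracy = h$train_accuracy[nrow(h)],
    best_val_accuracy = x$best_val_accuracy,
    seed = x$seed
  )
}

#' Tidy a Mann-Whitney U comparison
#'
#' @param x A `bs_mwu`.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `p.value`, `method`, `n`, `m`.
#' @export
tidy.bs_mwu <- function(x, ...) {
  tibble::tibble(statistic = x$U, p.value = x$p.value, method = x$method,
                 n = x$n, m = x$m)
}

#' Tidy a fine-tuning strategy report
#'
#' @param x A `bs_strategy_report`.
#' @param ... Unused.
#' @return A one-row tibble summarising the surgery.
#' @export
tidy.bs_strategy_report <- function(x, ...) {
  tibble::tibble(
    strategy = x$strategy,
    n_trainable = x$n_trainable,
    n_frozen = x$n_frozen,
    n_total = x$n_total,
    n_removed_layers = length(x$removed_layers),
    head_in = x$appended_head[1],
    head_out = x$appended_head[2]
  )
}

#' Training curves for a fit
#'
#' @param object A `bs_fit`.
#' @param ... Unused.
#' @return A ggplot of loss and accuracy per epoch.
#' @export
autoplot.bs_fit <- function(object, ...) {
  h <- object$history
  long <- rbind(
    tibble::tibble(epoch = h$epoch, metric = "train loss",
                   value = h$train_loss),
    tibble::tibble(epoch = h$epoch, metric = "train accuracy",
                   value = h$train_accuracy),
    tibble::tibble(epoch = h$epoch, metric = "validation accuracy",
                   value = h$val_accuracy)
  )
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = sprintf("Training history (%s)",
                                  object$model$family)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Heatmap of a feature matrix
#'
#' @param object A `bs_features`.
#' @param ... Unused.
#' @return A ggplot raster of coefficients over frames.
#' @export
autoplot.bs_features <- function(object, ...) {
  v <- object$values
  df <- tibble::tibble(
    frame = rep(seq_len(nrow(v)), times = ncol(v)),
    coefficient = rep(seq_len(ncol(v)), each = nrow(v)),
    value = as.numeric(v)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$coefficient,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "frame", y = "coefficient", fill = object$feature,
                  title = sprintf("%s features @ %g Hz", object$feature,
                                  object$sample_rate)) +
    ggplot2::theme_minimal()
}

#' Accuracy box plots for sweep results
#'
#' Box plot of per-run accuracy by model family, faceted by acoustic
#' feature — the standard way these model comparisons are displayed.
#'
#' @param object A `bs_sweep_results` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bs_sweep_results <- function(object, ...) {
  df <- object[!is.na(object$accuracy), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$accuracy,
                                   fill = .data$model)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~feature) +
    ggplot2::labs(x = NULL, y = "accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none",
                   axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
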