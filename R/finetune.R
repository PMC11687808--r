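#' A pretrained encoder as an ordered list of parameter groups
#'
#' The abstract interface the fine-tuning strategies operate on: a feature
#' extractor (an ordered list of named parameter groups) followed by
#' feature classification layers (another ordered list). Every parameter
#' belongs to exactly one group. The forward contract is a dense chain:
#' each group's weight matrix is applied in order with a tanh between
#' groups (heads appended by the strategies are linear).
#'
#' Real self-supervised speech encoders (HuBERT, wav2vec 2.0) can be
#' expressed in this interface by an adapter that lists their tensors in
#' order; the package's tests run entirely on small stand-in encoders so
#' the suite needs no downloads.
#'
#' @param feature_extractor Named list of groups; each group is a named
#'   list of numeric arrays (typically a single weight matrix `W`).
#' @param classification_layers Named list of groups, same structure.
#' @return A `bs_pretrained_encoder`.
#' @export
pretrained_encoder <- function(feature_extractor, classification_layers) {
  stopifnot(length(feature_extractor) > 0, length(classification_layers) > 0)
  structure(
    list(feature_extractor = feature_extractor,
         classification_layers = classification_layers),
    class = "bs_pretrained_encoder"
  )
}

group_n_params <- function(group) {
  sum(vapply(group, length, integer(1)))
}

#' Number of parameters per group of a pretrained encoder
#' @param encoder A [pretrained_encoder()].
#' @return Named list with `feature_extractor` and `classification_layers`
#'   integer vectors.
#' @export
encoder_param_counts <- function(encoder) {
  list(
    feature_extractor =
      vapply(encoder$feature_extractor, group_n_params, integer(1)),
    classification_layers =
      vapply(encoder$classification_layers, group_n_params, integer(1))
  )
}

#' A small stand-in pretrained encoder
#'
#' A dense-chain encoder used as the test surface for the fine-tuning
#' strategies: a two-group feature extractor (85 -> 10 -> 15, 1,000
#' parameters in total) and four classification layers
#' 15 -> 20 -> 10 -> 10 -> 5 holding 300, 200, 100 and 50 parameters.
#' All projections are bias-free so the group sizes are exact.
#'
#' @param seed Integer seed for the random weights.
#' @return A `bs_pretrained_encoder`.
#' @export
standin_encoder <- function(seed = 1) {
  withr::local_seed(seed)
  pretrained_encoder(
    feature_extractor = list(
      E1 = list(W = glorot(85, 10)),
      E2 = list(W = glorot(10, 15))
    ),
    classification_layers = list(
      L1 = list(W = glorot(15, 20)),
      L2 = list(W = glorot(20, 10)),
      L3 = list(W = glorot(10, 10)),
      L4 = list(W = glorot(10, 5))
    )
  )
}

#' Apply a fine-tuning strategy to a pretrained encoder
#'
#' The three layer-freezing recipes:
#'
#' * `FP` (full-parameter): every parameter stays trainable; a new
#'   `n_classes` head is appended.
#' * `LP1`: the feature extractor is frozen, the **last** classification
#'   layer is removed, and a new fully connected head is appended
#'   (trainable, as are the remaining classification layers).
#' * `LP2`: the feature extractor is frozen, the **last three**
#'   classification layers are removed, and a new fully connected head is
#'   appended.
#'
#' The appended head is a single fully connected layer (output width of
#' the last remaining layer `-> n_classes`, with bias).
#'
#' @param encoder A [pretrained_encoder()].
#' @param strategy `"FP"`, `"LP1"` or `"LP2"`.
#' @param n_classes Number of output classes for the new head.
#' @param seed Integer seed for the head initialisation.
#' @return A list with `model` (a trainable `bs_model` whose
#'   `meta$trainable` names the unfrozen tensors) and `report`
#'   (a `bs_strategy_report`).
#' @export
apply_strategy <- function(encoder, strategy = c("FP", "LP1", "LP2"),
                           n_classes = 2, seed = 1) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(encoder, "bs_pretrained_encoder"))
  n_remove <- switch(strategy, FP = 0L, LP1 = 1L, LP2 = 3L)
  cls <- encoder$classification_layers
  if (strategy == "LP2" && length(cls) < 3) {
    stop("LP2 requires at least 3 classification layers (found ",
         length(cls), ")", call. = FALSE)
  }
  removed <- character(0)
  if (n_remove > 0) {
    removed <- names(cls)[(length(cls) - n_remove + 1):length(cls)]
    cls <- cls[seq_len(length(cls) - n_remove)]
  }

  flatten <- function(groups, prefix) {
    out <- list()
    for (gn in names(groups)) {
      for (tn in names(groups[[gn]])) {
        out[[paste(prefix, gn, tn, sep = ".")]] <- groups[[gn]][[tn]]
      }
    }
    out
  }
  params <- c(flatten(encoder$feature_extractor, "extractor"),
              flatten(cls, "classifier"))

  # width at which the new head attaches: output of the last kept group
  kept <- c(encoder$feature_extractor, cls)
  last_W <- kept[[length(kept)]]
  hidden_width <- ncol(last_W[[length(last_W)]])
  withr::local_seed(seed)
  params[["head.W"]] <- glorot(hidden_width, n_classes)
  params[["head.b"]] <- rep(0, n_classes)

  trainable <- if (strategy == "FP") {
    names(params)
  } else {
    names(params)[!startsWith(names(params), "extractor.")]
  }
  frozen <- setdiff(names(params), trainable)
  n_trainable <- sum(vapply(params[trainable], length, integer(1)))
  n_frozen <- sum(vapply(params[frozen], length, integer(1)))

  order_groups <- names(kept)
  fwd <- function(params, prep, cfg, training = FALSE, buffers = NULL) {
    h <- as_ag_x(prep)
    for (nm in names(params)) {
      if (nm %in% c("head.W", "head.b")) next
      h <- ag_tanh(ag_matmul(h, params[[nm]]))
    }
    ag_add_bias(ag_matmul(h, params[["head.W"]]), params[["head.b"]])
  }
  prepare <- function(xlist) {
    x <- do.call(rbind, lapply(xlist, function(v) matrix(v, nrow = 1)))
    list(x = x, B = nrow(x), T = 1L)
  }
  model <- new_bs_model(paste0("finetune_", strategy), params, NULL,
                        fwd, prepare,
                        meta = list(trainable = trainable,
                                    strategy = strategy))

  report <- structure(
    list(strategy = strategy,
         n_trainable = as.integer(n_trainable),
         n_frozen = as.integer(n_frozen),
         n_total = as.integer(n_trainable + n_frozen),
         removed_layers = removed,
         appended_head = as.integer(c(hidden_width, n_classes)),
         n_head_params = as.integer(hidden_width * n_classes + n_classes),
         frozen_tensors = frozen,
         trainable_tensors = trainable),
    class = "bs_strategy_report"
  )
  list(model = model, report = report)
}

#' @export
print.bs_strategy_report <- function(x, ...) {
  cat(sprintf(
    "<%s: %d trainable / %d frozen params; removed [%s]; head %dx%d>\n",
    x$strategy, x$n_trainable, x$n_frozen,
    paste(x$removed_layers, collapse = ", "),
    x$appended_head[1], x$appended_head[2]))
  invisible(x)
}
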