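#' Stratified train / test / validation split
#'
#' Shuffles within each class under the given seed and assigns samples to
#' the three partitions with largest-remainder rounding, so partition sizes
#' follow the ratios exactly and the class balance is preserved to within
#' one sample per partition.
#'
#' @param segments A list of labelled items. Labels are taken from the
#'   `label` field of each element (or from `labels` if supplied).
#' @param ratios Numeric triple `(train, test, validation)`, each `> 0`,
#'   summing to 1.
#' @param seed Integer seed.
#' @param labels Optional explicit integer label vector.
#' @return A list with elements `train`, `test`, `validation`, each a list
#'   of the input items, plus an `indices` list of the original positions.
#' @export
split_dataset <- function(segments, ratios = c(0.8, 0.1, 0.1), seed = 1,
                          labels = NULL) {
  stopifnot(length(ratios) == 3, all(ratios > 0),
            abs(sum(ratios) - 1) < 1e-8)
  if (is.null(labels)) {
    labels <- vapply(segments, function(s) as.integer(s$label), integer(1))
  }
  if (length(unique(labels)) < 2) {
    stop("split_dataset needs at least one segment per class", call. = FALSE)
  }
  withr::local_seed(seed)
  parts <- list(integer(0), integer(0), integer(0))
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    raw <- ratios * n
    sizes <- floor(raw)
    rem <- n - sum(sizes)
    if (rem > 0) {
      order_frac <- order(raw - sizes, decreasing = TRUE)
      sizes[order_frac[seq_len(rem)]] <- sizes[order_frac[seq_len(rem)]] + 1
    }
    stops <- cumsum(sizes)
    starts <- c(1, stops[-3] + 1)
    for (k in 1:3) {
      if (sizes[k] > 0) {
        parts[[k]] <- c(parts[[k]], idx[starts[k]:stops[k]])
      }
    }
  }
  list(train = segments[parts[[1]]],
       test = segments[parts[[2]]],
       validation = segments[parts[[3]]],
       indices = list(train = parts[[1]], test = parts[[2]],
                      validation = parts[[3]]))
}

#' Confusion counts for binary predictions
#'
#' @param truth Integer vector of true labels (1 = bowel sound event,
#'   0 = non-event).
#' @param pred Integer vector of predicted labels.
#' @return A `bs_confusion` list with `TP`, `TN`, `FP`, `FN`, `P`, `N`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  structure(
    list(TP = sum(truth == 1 & pred == 1),
         TN = sum(truth == 0 & pred == 0),
         FP = sum(truth == 0 & pred == 1),
         FN = sum(truth == 1 & pred == 0),
         P = sum(truth == 1), N = sum(truth == 0)),
    class = "bs_confusion"
  )
}

#' Recognition accuracy
#'
#' `ACC = (TP + TN) / (P + N)`: the fraction of bowel-sound and
#' non-bowel-sound samples that the model identifies correctly.
#'
#' @param counts A `bs_confusion` from [confusion_counts()], or a list with
#'   fields `TP`, `TN`, `P`, `N`.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  tot <- counts$P + counts$N
  if (tot <= 0) stop("accuracy undefined: no evaluated samples",
                     call. = FALSE)
  (counts$TP + counts$TN) / tot
}

# ---- optimiser ----------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, trainable = NULL) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (!is.null(trainable) && !(nm %in% trainable)) next
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Training hyperparameters
#'
#' @param lr Adam learning rate.
#' @param epochs Maximum number of epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience in epochs on validation
#'   accuracy; `Inf` disables early stopping (the final-epoch weights are
#'   kept, which is the right choice when probing chance-level behaviour,
#'   because selecting the best validation epoch biases the estimate
#'   upward).
#' @return A list of settings.
#' @export
train_control <- function(lr = 1e-3, epochs = 30, batch_size = 32,
                          patience = 10) {
  list(lr = lr, epochs = epochs, batch_size = batch_size,
       patience = patience)
}

#' Train a model by minimising cross-entropy
#'
#' Minibatch Adam with optional early stopping on validation accuracy.
#' Fully reproducible: the seed drives shuffling, dropout and branch
#' dropout, so two runs with the same seed produce identical weights.
#'
#' @param model A `bs_model`.
#' @param x_train List of feature matrices (`bs_features` or matrices).
#' @param y_train Integer labels (0/1).
#' @param x_val,y_val Validation set (may be `NULL` to skip validation; early
#'   stopping is then disabled).
#' @param control A [train_control()].
#' @param seed Integer seed.
#' @param trainable Optional character vector naming the parameter tensors
#'   to update; all others stay frozen. `NULL` trains everything.
#' @return A `bs_fit`: the trained model plus a per-epoch `history` tibble
#'   (columns `epoch`, `train_loss`, `train_accuracy`, `val_accuracy`).
#' @export
train_model <- function(model, x_train, y_train, x_val = NULL, y_val = NULL,
                        control = train_control(), seed = 1,
                        trainable = NULL) {
  stopifnot(length(x_train) == length(y_train), length(x_train) > 0)
  withr::local_seed(seed)
  n <- length(x_train)
  y1 <- as.integer(y_train) + 1L   # class index 1/2
  state <- adam_state(model$params)
  best_val <- -Inf
  best_params <- model$params
  wait <- 0
  hist <- vector("list", control$epochs)
  has_val <- !is.null(x_val) && length(x_val) > 0
  prep_val <- if (has_val) model$prepare(x_val) else NULL
  epochs_run <- 0
  for (ep in seq_len(control$epochs)) {
    ord <- sample(n)
    ep_loss <- 0
    ep_correct <- 0
    for (start in seq(1, n, by = control$batch_size)) {
      idx <- ord[start:min(start + control$batch_size - 1, n)]
      prep <- model$prepare(x_train[idx])
      pa <- params_to_ag(model$params, trainable = trainable)
      logits <- model$forward(pa, prep, model$cfg, training = TRUE,
                              buffers = model$buffers)
      loss <- ag_softmax_cross_entropy(logits, y1[idx])
      if (!is.finite(loss$value)) {
        stop("training diverged: non-finite loss at epoch ", ep,
             " (lr = ", control$lr, ")", call. = FALSE)
      }
      ag_backward(loss)
      grads <- lapply(pa, function(p) p$grad)
      upd <- adam_step(model$params, grads, state, lr = control$lr,
                       trainable = trainable)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + loss$value * length(idx)
      pred <- max.col(logits$value) - 1L
      ep_correct <- ep_correct + sum(pred == y_train[idx])
    }
    val_acc <- NA_real_
    if (has_val) {
      pv <- params_to_ag(model$params, trainable = character(0))
      vlog <- model$forward(pv, prep_val, model$cfg, training = FALSE,
                            buffers = model$buffers)$value
      val_acc <- mean((max.col(vlog) - 1L) == y_val)
    }
    hist[[ep]] <- tibble::tibble(
      epoch = ep, train_loss = ep_loss / n,
      train_accuracy = ep_correct / n, val_accuracy = val_acc
    )
    epochs_run <- ep
    if (has_val && is.finite(control$patience)) {
      if (val_acc > best_val + 1e-12) {
        best_val <- val_acc
        best_params <- model$params
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= control$patience) break
      }
    }
  }
  if (has_val && is.finite(control$patience)) {
    model$params <- best_params
  }
  structure(
    list(model = model,
         history = do.call(rbind, hist[seq_len(epochs_run)]),
         best_val_accuracy = if (has_val) max(-Inf, best_val) else NA_real_,
         seed = seed, control = control),
    class = "bs_fit"
  )
}

#' @export
print.bs_fit <- function(x, ...) {
  cat(sprintf("<bs_fit %s: %d epochs, best val accuracy %s>\n",
              x$model$family, nrow(x$history),
              format(x$best_val_accuracy, digits = 4)))
  invisible(x)
}

#' Evaluate a model's accuracy on a labelled set
#'
#' @param model A `bs_model` (or a `bs_fit`).
#' @param x List of feature matrices.
#' @param y Integer labels (0/1).
#' @return A list with `accuracy` and the `bs_confusion` counts.
#' @export
evaluate_model <- function(model, x, y) {
  if (inherits(model, "bs_fit")) model <- model$model
  pred <- predict_label(model, x)
  counts <- confusion_counts(y, pred)
  list(accuracy = accuracy(counts), confusion = counts)
}

# ---- Mann-Whitney U -----------------------------------------------------

#' Mann-Whitney U test for two accuracy samples
#'
#' Two-sided rank-sum test used to compare the accuracy distributions of
#' two model families over repeated runs. `U` is computed by rank summation
#' with midranks for ties. The p-value uses the exact null distribution
#' (counting recursion over all arrangements) when `n * m <= 400` and the
#' data are tie-free; otherwise a normal approximation with tie correction
#' and continuity correction.
#'
#' @param acc_a,acc_b Numeric vectors (length `>= 3` each).
#' @return A `bs_mwu` list: `U` (for the first sample), `p.value`,
#'   `method`, `n`, `m`.
#' @export
mann_whitney_u <- function(acc_a, acc_b) {
  n <- length(acc_a)
  m <- length(acc_b)
  if (n < 3 || m < 3) {
    stop("mann_whitney_u needs at least 3 values per group", call. = FALSE)
  }
  r <- rank(c(acc_a, acc_b))
  U_a <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- anyDuplicated(c(acc_a, acc_b)) > 0
  if (!has_ties && n * m <= 400) {
    p <- mwu_exact_p(U_a, n, m)
    method <- "exact"
  } else {
    mu <- n * m / 2
    tie_tab <- table(r)
    N <- n + m
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      # every observation tied: no evidence against the null
      p <- 1
    } else {
      z <- (U_a - mu - sign(U_a - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  structure(list(U = U_a, p.value = p, method = method, n = n, m = m),
            class = "bs_mwu")
}

# exact null distribution of U via the standard counting recursion
# c(n, m, u) = c(n-1, m, u-m) + c(n, m-1, u): the largest observation is
# either from group A (contributing m to U) or from group B
mwu_counts <- function(n, m) {
  u_max <- n * m
  arr <- array(0, dim = c(n + 1, m + 1, u_max + 1))
  arr[1, , 1] <- 1
  arr[, 1, 1] <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      u <- 0:(i * j)
      from_a <- numeric(length(u))
      ok <- u - j >= 0
      from_a[ok] <- arr[i, j + 1, u[ok] - j + 1]
      arr[i + 1, j + 1, u + 1] <- from_a + arr[i + 1, j, u + 1]
    }
  }
  arr[n + 1, m + 1, ]
}

mwu_exact_p <- function(U, n, m) {
  counts <- mwu_counts(n, m)
  total <- sum(counts)
  u_int <- round(U)
  lower <- sum(counts[seq_len(u_int + 1)]) / total        # P(U <= u)
  upper <- sum(counts[(u_int + 1):(n * m + 1)]) / total   # P(U >= u)
  min(1, 2 * min(lower, upper))
}

#' @export
print.bs_mwu <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, m = %d), p = %.4g [%s]\n",
              x$U, x$n, x$m, x$p.value, x$method))
  invisible(x)
}

#' Significance annotation used in accuracy comparisons
#'
#' Maps a p-value to the star annotation levels used when reporting
#' between-model accuracy differences (0.01, 0.001, 0.0001). No
#' multiple-testing correction is applied.
#'
#' @param p A p-value.
#' @return `"ns"`, `"**"`, `"***"` or `"****"`.
#' @export
significance_label <- function(p) {
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***"
  else if (p <= 1e-2) "**" else "ns"
}
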