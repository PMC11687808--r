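#' The one-factor-at-a-time replication grid
#'
#' Builds the standard experiment grid: five axes (sampling rate `sr`,
#' frame length `fl`, frame shift `fs`, feature length `tl`, window), each
#' swept over three settings while the other axes sit at their baseline
#' values (`sr` 44100, `fl` 1024, `fs` 441, `tl` 164, window hamming),
#' crossed with three acoustic features and five model families:
#' 5 axes x 3 settings x 3 features x 5 models = 225 cells.
#'
#' @param models Model families to include.
#' @param features Feature families to include.
#' @return A `bs_sweep_grid` tibble, one row per cell, with a unique
#'   `cell_id`.
#' @export
sweep_grid <- function(models = c("cnn", "lstm", "cnn_lstm", "resnet34",
                                  "branchformer"),
                       features = c("mfcc", "lpc", "mel")) {
  axes <- list(
    sr = c(8000, 22050, 44100),
    fl = c(1024, 1323, 1764),
    fs = c(441, 529, 661),
    tl = c(131, 164, 199),
    window = c("hanning", "hamming", "rectangle")
  )
  base <- list(sr = 44100, fl = 1024, fs = 441, tl = 164,
               window = "hamming")
  rows <- list()
  for (axis in names(axes)) {
    for (setting in axes[[axis]]) {
      cell <- base
      cell[[axis]] <- setting
      for (feat in features) {
        for (mod in models) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            table = axis, model = mod, feature = feat,
            sr = as.numeric(cell$sr), fl = as.integer(cell$fl),
            fs = as.integer(cell$fs), tl = as.integer(cell$tl),
            window = cell$window,
            cell_id = paste(axis, setting, feat, mod, sep = "_")
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bs_sweep_grid", class(out))
  out
}

# stable 31-adic string hash, kept below 2^31
cell_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  h
}

#' Seed for one (cell, repeat) run
#' @param base_seed Sweep-level base seed.
#' @param cell_id Cell identifier string.
#' @param rep Repeat index.
#' @return Integer seed below 2^31.
#' @export
run_seed <- function(base_seed, cell_id, rep) {
  as.integer((base_seed + cell_hash(paste0(cell_id, "#", rep))) %%
               2147483647)
}

#' Run an experiment sweep over feature / model / preprocessing settings
#'
#' Executes every (cell, repeat) of the grid: regenerates (or loads) the
#' labelled segments at the cell's sampling rate, preprocesses them (peak
#' normalisation + pre-emphasis), extracts the cell's acoustic feature,
#' splits the data, trains the cell's model, and records test accuracy.
#' Results are appended to `out_csv` after every run, and a rerun skips
#' (cell, repeat) pairs already present in that file, so an interrupted
#' sweep resumes where it stopped. A failing cell is recorded with an
#' `NA` accuracy and its error message; the sweep continues.
#'
#' @param grid A [sweep_grid()] tibble (or any tibble with its columns).
#' @param data_source Function `(sr, seed)` returning a list of labelled
#'   `bs_segment` objects at sampling rate `sr`.
#' @param n_repeats Runs per cell (distinct seeds).
#' @param base_seed Base seed; each run's seed is derived from it and the
#'   cell id via [run_seed()].
#' @param out_csv Optional path for incremental results; `NULL` keeps
#'   results in memory only (no resume).
#' @param control A [train_control()].
#' @param split_ratios Train/test/validation fractions.
#' @param encoder_cfg [encoder_config()] used for Branchformer cells.
#' @param baseline_width Width of the compact baseline families.
#' @param resnet_base_width Stage-1 width for ResNet-34 cells.
#' @param feature_cfg Optional [feature_config()] overriding the feature
#'   dimensions (the feature family is still taken from each cell).
#' @param pre_emphasis Pre-emphasis coefficient applied before framing.
#' @param verbose Print one line per run.
#' @return A `bs_sweep_results` tibble: one row per (cell, repeat) with
#'   the cell settings, `rep`, `seed`, `accuracy` and `error`.
#' @export
run_sweep <- function(grid, data_source, n_repeats = 1, base_seed = 1,
                      out_csv = NULL, control = train_control(),
                      split_ratios = c(0.8, 0.1, 0.1),
                      encoder_cfg = encoder_config(d = 32, n_blocks = 2),
                      baseline_width = 16, resnet_base_width = 8,
                      feature_cfg = NULL, pre_emphasis = 0.97,
                      verbose = FALSE) {
  done <- character(0)
  results <- list()
  if (!is.null(out_csv) && file.exists(out_csv)) {
    prev <- utils::read.csv(out_csv, stringsAsFactors = FALSE)
    if (nrow(prev) > 0) {
      done <- paste(prev$cell_id, prev$rep, sep = "@")
      results <- list(tibble::as_tibble(prev))
    }
  }
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    for (rp in seq_len(n_repeats)) {
      key <- paste(cell$cell_id, rp, sep = "@")
      if (key %in% done) next
      seed <- run_seed(base_seed, cell$cell_id, rp)
      acc <- NA_real_
      err <- NA_character_
      res <- tryCatch(
        run_cell(cell, data_source, seed, control, split_ratios,
                 encoder_cfg, baseline_width, resnet_base_width,
                 feature_cfg, pre_emphasis),
        error = function(e) conditionMessage(e)
      )
      if (is.numeric(res)) acc <- res else err <- res
      row <- tibble::tibble(
        table = cell$table, cell_id = cell$cell_id, model = cell$model,
        feature = cell$feature, sr = cell$sr, fl = cell$fl, fs = cell$fs,
        tl = cell$tl, window = cell$window, rep = rp, seed = seed,
        accuracy = acc, error = err
      )
      results[[length(results) + 1]] <- row
      if (!is.null(out_csv)) {
        new_file <- !file.exists(out_csv)
        utils::write.table(row, out_csv, sep = ",", row.names = FALSE,
                           col.names = new_file, append = !new_file)
      }
      if (verbose) {
        message(sprintf("[%s rep %d] acc = %s", cell$cell_id, rp,
                        format(acc, digits = 4)))
      }
    }
  }
  out <- do.call(rbind, results)
  class(out) <- c("bs_sweep_results", class(out))
  out
}

run_cell <- function(cell, data_source, seed, control, split_ratios,
                     encoder_cfg, baseline_width, resnet_base_width,
                     feature_cfg, pre_emphasis) {
  segments <- data_source(sr = cell$sr, seed = seed)
  feats <- lapply(segments, function(seg) {
    clip <- pre_emphasize(peak_normalize(seg$clip), pre_emphasis)
    extract_features(clip, feature = cell$feature, fl = cell$fl,
                     fs = cell$fs, tl = cell$tl, window = cell$window,
                     cfg = feature_cfg)
  })
  y <- vapply(segments, function(s) as.integer(s$label), integer(1))
  sp <- split_dataset(seq_along(segments), ratios = split_ratios,
                      seed = seed, labels = y)
  n_coeffs <- ncol(feats[[1]]$values)
  model <- build_model(cell$model, c(cell$tl, n_coeffs), seed = seed,
                       encoder_cfg = encoder_cfg,
                       width = baseline_width,
                       base_width = resnet_base_width)
  idx <- sp$indices
  fit <- train_model(model,
                     feats[idx$train], y[idx$train],
                     feats[idx$validation], y[idx$validation],
                     control = control, seed = seed)
  evaluate_model(fit, feats[idx$test], y[idx$test])$accuracy
}

#' Compare model families' sweep accuracies against a reference family
#'
#' Runs a two-sided Mann-Whitney U test of each family's accuracy
#' distribution against the reference (by default the Branchformer),
#' pooling all successful runs, and annotates the significance level.
#'
#' @param results A `bs_sweep_results` tibble.
#' @param reference Reference model family.
#' @return A tibble with one row per other family: `model`, `n`, median
#'   accuracies, `U`, `p.value`, `signif`.
#' @export
compare_families <- function(results, reference = "branchformer") {
  results <- results[!is.na(results$accuracy), ]
  ref_acc <- results$accuracy[results$model == reference]
  others <- setdiff(unique(results$model), reference)
  rows <- lapply(others, function(fam) {
    acc <- results$accuracy[results$model == fam]
    mw <- mann_whitney_u(ref_acc, acc)
    tibble::tibble(model = fam, n = length(acc),
                   median_ref = stats::median(ref_acc),
                   median_model = stats::median(acc),
                   U = mw$U, p.value = mw$p.value,
                   signif = significance_label(mw$p.value))
  })
  do.call(rbind, rows)
}
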