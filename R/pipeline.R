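#' Train and evaluate a family of architectures
#'
#' Runs one Kim-Monte Carlo training session per architecture and evaluates
#' each trained model on the test set, pooling per-box scores. The
#' fully-connected family defaults to the full 45-model sweep
#' (5 resolutions x 3 widths x 3 depths); the convolution family to the
#' 2 x 2 grid of head depths {1, 2} x head activations {sigmoid, relu}.
#' Per-model seeds are derived deterministically from `seed` so reruns are
#' bit-identical.
#'
#' @param train,test `labeled_dataset`s (see [split_train_test()]).
#' @param family `"ann"` or `"cnn"`.
#' @param specs for `"ann"`, a list of [ann_spec()]s (default
#'   [enumerate_sweep()]); for `"cnn"`, a data frame with columns
#'   `n_hidden` (1 or 2) and `activation` (default the 2 x 2 grid).
#' @param control a [kmc_control()].
#' @param seed integer master seed.
#' @param verbose print progress per model.
#' @return multi-row `eval_report` data frame sorted by AUC descending,
#'   with attribute `"best"` holding the [best_model()] row and attribute
#'   `"fits"` the list of `kmc_fit` objects (in spec order).
#' @export
run_sweep <- function(train, test, family = c("ann", "cnn"), specs = NULL,
                      control = kmc_control(), seed = 1L, verbose = FALSE) {
  family <- match.arg(family)
  if (length(train) == 0L || length(test) == 0L)
    stop("train and test sets must be nonempty")
  if (family == "ann") {
    if (is.null(specs)) specs <- enumerate_sweep()
    resolutions <- unique(vapply(specs, `[[`, integer(1), "resolution"))
    prep_train <- lapply(resolutions, function(r) prep_dataset(train, r))
    prep_test <- lapply(resolutions, function(r) prep_dataset(test, r))
    names(prep_train) <- names(prep_test) <- as.character(resolutions)
    fits <- vector("list", length(specs))
    rows <- vector("list", length(specs))
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      key <- as.character(sp$resolution)
      net <- build_ann(sp, seed = seed + i)
      fit <- kmc_train(net, prep_train[[key]]$x, prep_train[[key]]$y,
                       control = control, seed = seed + 1000L + i)
      rows[[i]] <- evaluate_model(fit, prep_test[[key]],
                                  model_id = format(sp))
      fits[[i]] <- fit
      if (verbose)
        message(sprintf("[%2d/%2d] %s: AUC %.3f", i, length(specs),
                        format(sp), rows[[i]]$auc))
    }
  } else {
    if (is.null(specs))
      specs <- expand.grid(n_hidden = 1:2,
                           activation = c("bipolar_sigmoid", "relu"),
                           stringsAsFactors = FALSE)
    side <- nrow(train[[1]]$pixels)
    res <- max(64L, 64L * (side %/% 64L))
    prep_train <- prep_dataset(train, res)
    prep_test <- prep_dataset(test, res)
    fits <- vector("list", nrow(specs))
    rows <- vector("list", nrow(specs))
    for (i in seq_len(nrow(specs))) {
      widths <- rep(49L, specs$n_hidden[i])
      net <- build_cnn(widths, specs$activation[i], input_size = res,
                       seed = seed + i)
      fit <- kmc_train(net, prep_train$x, prep_train$y,
                       control = control, seed = seed + 1000L + i)
      id <- sprintf("cnn-%s-%s", specs$activation[i],
                    paste(widths, collapse = "-"))
      rows[[i]] <- evaluate_model(fit, prep_test, model_id = id)
      fits[[i]] <- fit
      if (verbose)
        message(sprintf("[%d/%d] %s: AUC %.3f", i, nrow(specs), id,
                        rows[[i]]$auc))
    }
  }
  reports <- do.call(rbind, rows)
  reports <- reports[order(-reports$auc, -reports$accuracy,
                           reports$model), , drop = FALSE]
  rownames(reports) <- NULL
  class(reports) <- c("eval_report", "data.frame")
  attr(reports, "best") <- best_model(reports)
  attr(reports, "fits") <- fits
  reports
}

#' Select the best report row
#'
#' Maximal AUC; ties broken by accuracy, then lexically by model id.
#'
#' @param reports an `eval_report` data frame with at least one row.
#' @return the winning one-row `eval_report`.
#' @export
best_model <- function(reports) {
  df <- as.data.frame(reports)
  attr(df, "best") <- NULL
  attr(df, "fits") <- NULL
  if (nrow(df) == 0L) stop("empty report collection")
  ord <- order(-df$auc, -df$accuracy, df$model)
  out <- df[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "degenerate") <- NULL
  class(out) <- c("eval_report", "data.frame")
  out
}
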