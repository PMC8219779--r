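#' Control parameters for Kim-Monte Carlo training
#'
#' A training session runs `n_cycles` cycles; within cycle c the variable
#' selection ratio decays geometrically from `ratio_start` (15% of all
#' weights and biases) to `ratio_end` (1.5%). Each cycle holds
#' `round((ratio_budget / n_cycles) / ratio_c)` selection events so that the
#' per-cycle ratio sum is about `ratio_budget / n_cycles` and the session
#' total of selection ratios is about `ratio_budget` (900%). Each event
#' draws one random variable subset and makes `attempts_per_event`
#' perturbation attempts on it; an attempt is kept only when it strictly
#' decreases the mean training error over the full training set.
#'
#' @param weight_init_range initial weight range (uniform).
#' @param bias_init_range initial bias range (uniform, non-negative).
#' @param perturb_range additive perturbation range (uniform).
#' @param n_cycles cycles per session.
#' @param ratio_start,ratio_end first and last cycle selection ratios.
#' @param ratio_budget session total of selection ratios (9 = 900%).
#' @param attempts_per_event perturbation attempts per selection event.
#' @param error_kind training error functional; `"mse"` is the mean over
#'   all samples and all 49 outputs of the squared output-target difference.
#' @return object of class `kmc_control`.
#' @export
kmc_control <- function(weight_init_range = c(-0.2, 0.2),
                        bias_init_range = c(0, 0.2),
                        perturb_range = c(-0.1, 0.1),
                        n_cycles = 10L,
                        ratio_start = 0.15,
                        ratio_end = 0.015,
                        ratio_budget = 9,
                        attempts_per_event = 30L,
                        error_kind = "mse") {
  if (ratio_end > ratio_start || ratio_start <= 0 || ratio_end <= 0)
    stop("selection ratios must satisfy 0 < ratio_end <= ratio_start")
  if (ratio_budget <= 0) stop("'ratio_budget' must be positive")
  if (diff(weight_init_range) < 0 || diff(bias_init_range) < 0 ||
      diff(perturb_range) < 0)
    stop("ranges must be ordered (low, high)")
  if (!identical(error_kind, "mse"))
    stop("only error_kind = 'mse' is implemented")
  structure(list(weight_init_range = weight_init_range,
                 bias_init_range = bias_init_range,
                 perturb_range = perturb_range,
                 n_cycles = as.integer(n_cycles),
                 ratio_start = ratio_start, ratio_end = ratio_end,
                 ratio_budget = ratio_budget,
                 attempts_per_event = as.integer(attempts_per_event),
                 error_kind = error_kind),
            class = "kmc_control")
}

#' Selection-ratio schedule of a training session
#'
#' @param control a [kmc_control()].
#' @return data frame with columns `cycle`, `ratio`, `n_events`. Ratios are
#'   geometric from `ratio_start` to `ratio_end`; event counts keep each
#'   cycle's ratio sum near `ratio_budget / n_cycles`.
#' @examples
#' s <- cycle_schedule(kmc_control())
#' s$ratio[c(1, 10)]              # 0.150, 0.015
#' sum(s$ratio * s$n_events)      # about 9 (900%)
#' @export
cycle_schedule <- function(control) {
  n <- control$n_cycles
  ratio <- if (n == 1L) control$ratio_start else
    control$ratio_start *
      (control$ratio_end / control$ratio_start)^((seq_len(n) - 1) / (n - 1))
  per_cycle <- control$ratio_budget / n
  data.frame(cycle = seq_len(n), ratio = ratio,
             n_events = pmax(1L, as.integer(round(per_cycle / ratio))))
}

#' Mean training error of a network on a dataset
#'
#' The mean over all samples and all 49 output nodes of the squared
#' difference between network output and box target.
#'
#' @param net a `kmc_network`.
#' @param x input matrix (one row per sample).
#' @param y binary target matrix (same rows, 49 columns).
#' @return non-negative scalar.
#' @export
mean_training_error <- function(net, x, y) {
  if (NROW(x) == 0L) stop("empty training set")
  out <- forward_net(net, x)
  if (!all(dim(out) == dim(y))) stop("output/target shape mismatch")
  mean((out - y)^2)
}

# Draw ceil(ratio * V) distinct indices uniformly from the unified
# parameter vector of length V. Consumes the current RNG stream.
select_variables <- function(n_params, ratio) {
  if (ratio <= 0 || ratio > 1) stop("'ratio' must be in (0, 1]")
  sample.int(n_params, ceiling(ratio * n_params))
}

# Perturb the selected scalars by independent uniform increments; a bias
# that would become negative is flipped to its absolute value (weights keep
# their sign). Consumes the current RNG stream.
perturb_params <- function(params, idx, bias_mask, range = c(-0.1, 0.1)) {
  params[idx] <- params[idx] + runif(length(idx), range[1], range[2])
  flip <- idx[bias_mask[idx] & params[idx] < 0]
  params[flip] <- abs(params[flip])
  params
}

#' Train a network by the Kim-Monte Carlo algorithm
#'
#' Derivative-free random optimization: the unified pool of weights and
#' biases (convolution filters included) is repeatedly sampled at the
#' scheduled selection ratio; the selected variables are perturbed by small
#' uniform amounts (biases flipped positive if an adjustment would make
#' them negative), and the adjustment is accepted only when it strictly
#' decreases the mean training error on the full training set. Accepted
#' attempts compound within an event; rejected ones are reverted.
#'
#' @param net a freshly built `kmc_network` (see [build_ann()],
#'   [build_cnn()]).
#' @param x training input matrix, one row per sample, values in `[0, 1]`
#'   (see [prep_dataset()]).
#' @param y training target matrix, `nrow(x)` x 49, values in `{0, 1}`.
#' @param control a [kmc_control()].
#' @param seed integer seed; the whole session is bit-reproducible given
#'   (net, x, y, control, seed).
#' @param verbose print one line per cycle.
#' @return an object of class `kmc_fit` with components `network` (the
#'   trained `kmc_network`), `initial_error`, `final_error`, `trace` (data
#'   frame of accepted steps: cycle, event, attempt, error), `schedule`,
#'   `control`, `seed`, `fitted` (training outputs of the final network),
#'   `y` (training targets) and `call`.
#' @examples
#' ds <- generate_dataset(synth_config(n_images = 8, image_size = 70, seed = 3))
#' pp <- prep_dataset(ds, 20)
#' fit <- kmc_train(build_ann(ann_spec(20, 49, 1), seed = 1), pp$x, pp$y,
#'                  control = kmc_control(n_cycles = 2, attempts_per_event = 5),
#'                  seed = 1)
#' fit$final_error <= fit$initial_error
#' @export
kmc_train <- function(net, x, y, control = kmc_control(), seed = 1L,
                      verbose = FALSE) {
  stopifnot(inherits(net, "kmc_network"), inherits(control, "kmc_control"))
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (is.vector(y)) y <- matrix(y, nrow = 1L)
  if (NROW(x) == 0L) stop("empty training set")
  if (nrow(x) != nrow(y) || ncol(y) != net$output_size)
    stop("x and y shapes are inconsistent with the network")

  set.seed(seed)
  params <- net_params(net)
  bias_mask <- net_bias_mask(net)
  sched <- cycle_schedule(control)

  current_error <- mean_training_error(net, x, y)
  if (!is.finite(current_error)) stop("non-finite initial training error")
  initial_error <- current_error

  trace <- list()
  for (c_idx in seq_len(nrow(sched))) {
    for (e_idx in seq_len(sched$n_events[c_idx])) {
      idx <- select_variables(length(params), sched$ratio[c_idx])
      for (a_idx in seq_len(control$attempts_per_event)) {
        candidate <- perturb_params(params, idx, bias_mask,
                                    control$perturb_range)
        cand_net <- net_set_params(net, candidate)
        err <- mean_training_error(cand_net, x, y)
        if (!is.finite(err))
          stop("non-finite training error at cycle ", c_idx,
               ", event ", e_idx, ", attempt ", a_idx)
        if (err < current_error) {
          params <- candidate
          net <- cand_net
          current_error <- err
          trace[[length(trace) + 1L]] <-
            data.frame(cycle = c_idx, event = e_idx, attempt = a_idx,
                       error = err)
        }
      }
    }
    if (verbose)
      message(sprintf("cycle %2d: ratio %.4f, %3d events, error %.6f",
                      c_idx, sched$ratio[c_idx], sched$n_events[c_idx],
                      current_error))
  }

  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(cycle = integer(), event = integer(), attempt = integer(),
               error = numeric())
  structure(list(network = net,
                 initial_error = initial_error,
                 final_error = current_error,
                 trace = trace,
                 schedule = sched,
                 control = control,
                 seed = as.integer(seed),
                 fitted = forward_net(net, x),
                 y = y,
                 call = match.call()),
            class = "kmc_fit")
}

#' @export
print.kmc_fit <- function(x, ...) {
  cat("Kim-Monte Carlo training session\n")
  print(x$network)
  cat(sprintf("  %d cycles, %d events, %d accepted steps\n",
              x$control$n_cycles, sum(x$schedule$n_events), nrow(x$trace)))
  cat(sprintf("  training error: %.6f -> %.6f (ratio %.3f)\n",
              x$initial_error, x$final_error,
              x$final_error / x$initial_error))
  invisible(x)
}

#' @export
summary.kmc_fit <- function(object, ...) {
  per_cycle <- if (nrow(object$trace))
    as.vector(table(factor(object$trace$cycle,
                           levels = object$schedule$cycle)))
  else rep(0L, nrow(object$schedule))
  out <- list(schedule = cbind(object$schedule, accepted = per_cycle),
              initial_error = object$initial_error,
              final_error = object$final_error,
              n_accepted = nrow(object$trace),
              n_attempts = sum(object$schedule$n_events) *
                object$control$attempts_per_event,
              parameters = count_parameters(object$network))
  class(out) <- "summary.kmc_fit"
  out
}

#' @export
print.summary.kmc_fit <- function(x, ...) {
  cat("Kim-Monte Carlo training summary\n")
  cat(sprintf("  parameters: %d weights + %d biases\n",
              x$parameters["n_weights"], x$parameters["n_biases"]))
  cat(sprintf("  accepted %d of %d perturbation attempts\n",
              x$n_accepted, x$n_attempts))
  cat(sprintf("  training error %.6f -> %.6f\n\n",
              x$initial_error, x$final_error))
  print(x$schedule, row.names = FALSE)
  invisible(x)
}

#' @export
coef.kmc_fit <- function(object, ...) net_params(object$network)

#' Predict box scores for new images
#'
#' @param object a `kmc_fit`.
#' @param newdata a preprocessed input matrix (rows of length
#'   `input_size`), a `prep_dataset()` list, or a `labeled_dataset` (which
#'   is preprocessed at the network's resolution).
#' @param ... unused.
#' @return matrix of scores in (0, 1), one row per image, 49 columns
#'   (row-major box order).
#' @export
predict.kmc_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  x <- if (inherits(newdata, "labeled_dataset"))
    prep_dataset(newdata, object$network$resolution)$x
  else if (is.list(newdata) && !is.null(newdata$x)) newdata$x
  else newdata
  forward_net(object$network, x)
}

#' @export
residuals.kmc_fit <- function(object, ...) object$y - object$fitted

#' Plot the training-error trace of a session
#'
#' Draws the mean training error of every accepted step against the running
#' attempt index, with cycle boundaries marked.
#'
#' @param x a `kmc_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.kmc_fit <- function(x, ...) {
  tr <- x$trace
  errs <- c(x$initial_error, tr$error)
  graphics::plot(seq_along(errs) - 1L, errs, type = "s",
                 xlab = "accepted step", ylab = "mean training error",
                 main = "Kim-Monte Carlo training trace", ...)
  graphics::points(seq_along(errs) - 1L, errs, pch = 20, cex = 0.5)
  invisible(x)
}
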