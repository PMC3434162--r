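#' Training configuration
#'
#' @param penalty_grid candidate Gaussian-prior constants `c`.
#' @param split_fraction fraction of positive examples used for
#'   parameter optimization; the remainder selects the penalty.
#' @param rng_seed seed driving the split and negative sampling.
#' @param grad_tol projected-gradient stopping tolerance.
#' @param max_iter iteration cap for the quasi-Newton optimizer.
#' @param threshold_grid probability thresholds swept when scoring a
#'   candidate penalty by maximum F-score.
#' @param min_segment,max_segment hairpin segment length bounds used
#'   during penalty selection (see [call_hairpins()]).
#' @return an object of class `training_config`.
#' @export
training_config <- function(penalty_grid = c(0.1, 1, 10, 50, 100),
                            split_fraction = 0.8, rng_seed = 1L,
                            grad_tol = 1e-5, max_iter = 500L,
                            threshold_grid = seq(0.05, 0.95, by = 0.05),
                            min_segment = 80L, max_segment = 150L) {
  stopifnot(length(penalty_grid) >= 1L, all(penalty_grid > 0),
            split_fraction > 0, split_fraction < 1)
  structure(list(penalty_grid = penalty_grid,
                 split_fraction = split_fraction,
                 rng_seed = as.integer(rng_seed), grad_tol = grad_tol,
                 max_iter = as.integer(max_iter),
                 threshold_grid = threshold_grid,
                 min_segment = as.integer(min_segment),
                 max_segment = as.integer(max_segment)),
            class = "training_config")
}

#' Fit CRF parameters by penalized maximum likelihood
#'
#' Maximizes the label-constrained conditional log-likelihood with a
#' Gaussian prior by limited-memory quasi-Newton ascent (L-BFGS), from
#' the all-zero start. Deterministic for fixed inputs.
#'
#' @param examples list of [labeled_example()].
#' @param c Gaussian-prior constant.
#' @param graph a [state_graph()].
#' @param config a [training_config()].
#' @return a [crf_params()] with attributes `converged`, `objective`
#'   (final value) and `trace` (objective per evaluation).
#' @export
crf_fit <- function(examples, c, graph, config = training_config()) {
  stopifnot(length(examples) >= 1L)
  p0 <- crf_params(graph)
  trace <- numeric()
  cache <- new.env(parent = emptyenv())
  eval_at <- function(m) {
    obj <- penalized_objective(crf_params(graph, m), examples, c, graph)
    trace[length(trace) + 1L] <<- obj$value
    cache$last <- list(m = m, obj = obj)
    obj
  }
  fn <- function(m) {
    if (!is.null(cache$last) && identical(cache$last$m, m))
      return(-cache$last$obj$value)
    -eval_at(m)$value
  }
  gr <- function(m) {
    if (!is.null(cache$last) && identical(cache$last$m, m))
      return(-cache$last$obj$gradient)
    -eval_at(m)$gradient
  }
  res <- optim(p0$m, fn, gr, method = "L-BFGS-B",
               control = list(maxit = config$max_iter,
                              pgtol = config$grad_tol,
                              factr = 1e7))
  if (res$convergence != 0L)
    warning("optimizer did not converge: ", res$message,
            " (returning best iterate)")
  out <- crf_params(graph, res$par)
  attr(out, "converged") <- res$convergence == 0L
  attr(out, "objective") <- -res$value
  attr(out, "trace") <- trace
  out
}

.is_positive_example <- function(ex) any(ex$labels != "N")

.truth_interval <- function(ex) {
  hit <- which(ex$labels != "N")
  if (!length(hit)) return(NULL)
  c(min(hit), max(hit))
}

# maximum F-score over the threshold grid for a fitted model on
# held-out examples, counting hairpin-instance detections
.max_f_on_examples <- function(params, graph, examples, config) {
  pmi <- lapply(examples, function(ex) {
    post <- forward_backward(params, graph, ex$symbols)
    hairpin_probability(post, graph)
  })
  truths <- lapply(examples, .truth_interval)
  best <- list(f = -Inf, threshold = NA_real_)
  f_sweep <- numeric()
  for (T_ in config$threshold_grid) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (e in seq_along(examples)) {
      segs <- call_hairpins(pmi[[e]], T_,
                            min_length = config$min_segment,
                            max_length = config$max_segment)
      tr <- truths[[e]]
      if (is.null(tr)) {
        fp <- fp + nrow(segs)
      } else {
        hit <- nrow(segs) > 0 &&
          any(pmin(segs$end, tr[2]) - pmax(segs$start, tr[1]) + 1L > 0L)
        tp <- tp + as.integer(hit)
        fn <- fn + as.integer(!hit)
        if (nrow(segs) > 0L)
          fp <- fp + sum(pmin(segs$end, tr[2]) -
                           pmax(segs$start, tr[1]) + 1L <= 0L)
      }
    }
    m <- .metrics_from_counts(tp, fp, fn)
    f_sweep[length(f_sweep) + 1L] <- if (is.na(m$f)) 0 else m$f
    if (is.finite(m$f) && m$f > best$f)
      best <- list(f = m$f, threshold = T_)
  }
  best$mean_f <- mean(f_sweep)
  best
}

#' Select the Gaussian-prior constant by held-out F-score
#'
#' Splits the examples into a training group (a `split_fraction` sample
#' of the positives plus an equal number of negatives) and a validation
#' group (the remainder). For each candidate `c`, parameters are fitted
#' on the training group and the validation group is scanned; the
#' maximum F-score across the threshold grid scores the candidate. The
#' `c` with the best score wins.
#'
#' @param examples list of [labeled_example()] (positives carry
#'   non-`N` labels; negatives are all-`N`).
#' @param graph a [state_graph()].
#' @param config a [training_config()].
#' @return list with `c_best`, `params_best`, and a `report` data frame
#'   (one row per candidate: `c`, `max_f`, `best_threshold`).
#' @export
select_penalty <- function(examples, graph, config = training_config()) {
  pos <- which(vapply(examples, .is_positive_example, logical(1)))
  neg <- setdiff(seq_along(examples), pos)
  if (length(pos) < 2L || length(neg) < 2L)
    stop("need at least 2 positive and 2 negative examples")
  set.seed(config$rng_seed)
  n_tr_pos <- max(1L, round(config$split_fraction * length(pos)))
  if (n_tr_pos >= length(pos)) n_tr_pos <- length(pos) - 1L
  tr_pos <- sort(sample(pos, n_tr_pos))
  tr_neg <- sort(sample(neg, min(length(neg) - 1L, n_tr_pos)))
  va <- setdiff(seq_along(examples), c(tr_pos, tr_neg))
  if (!length(va)) stop("validation group is empty")
  train_set <- examples[c(tr_pos, tr_neg)]
  val_set <- examples[va]

  report <- data.frame(c = config$penalty_grid, max_f = NA_real_,
                       mean_f = NA_real_, best_threshold = NA_real_)
  fits <- vector("list", length(config$penalty_grid))
  for (ci in seq_along(config$penalty_grid)) {
    fits[[ci]] <- crf_fit(train_set, config$penalty_grid[ci], graph,
                          config)
    best <- .max_f_on_examples(fits[[ci]], graph, val_set, config)
    report$max_f[ci] <- best$f
    report$mean_f[ci] <- best$mean_f
    report$best_threshold[ci] <- best$threshold
  }
  # maximum F wins; ties break on mean F over the sweep, then on the
  # weaker prior (larger c)
  ord <- order(-report$max_f, -report$mean_f, -report$c)
  ci_best <- ord[1L]
  list(c_best = config$penalty_grid[ci_best],
       params_best = fits[[ci_best]], report = report,
       split = list(train = c(tr_pos, tr_neg), validation = va))
}
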