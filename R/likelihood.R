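#' Labeled training example
#'
#' A symbol sequence with one label per position in `{M,P,L,F,N}`
#' (mature, passenger, loop, flanking, non-miRNA). Labels are checked
#' for structural compatibility with the default graph (M/P runs of
#' 18-25 nt, F runs of exactly 20, L runs of at least 8); violations are
#' reported by [validate_labels()].
#'
#' @param symbols integer matrix T x 7 of symbol indices (a
#'   `symbol_sequence`).
#' @param labels character vector of per-position labels.
#' @param id provenance identifier.
#' @return an object of class `labeled_example`.
#' @export
labeled_example <- function(symbols, labels, id = NA_character_) {
  symbols <- unclass(symbols)
  stopifnot(is.matrix(symbols), ncol(symbols) == 7L,
            nrow(symbols) == length(labels))
  if (!all(labels %in% names(.label_codes)))
    stop("labels must be in {M,P,L,F,N}")
  structure(list(symbols = symbols, labels = labels, id = id),
            class = "labeled_example")
}

#' Report structural label violations
#'
#' @param labels character label vector.
#' @param arch an [arch_config()] defining the admissible run lengths.
#' @return character vector of human-readable violations (empty if none).
#' @export
validate_labels <- function(labels, arch = arch_config()) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_strand <- min(arch$skip_from) + 1L
  probs <- character()
  for (k in seq_along(r$values)) {
    v <- r$values[k]; len <- r$lengths[k]
    bad <- switch(v,
      M = len < min_strand || len > arch$n_mature,
      P = len < min_strand || len > arch$n_passenger,
      F = len != arch$n_flank,
      L = len < arch$n_loop,
      FALSE)
    if (bad)
      probs <- c(probs, sprintf("%s-run of %d at position %d", v, len,
                                starts[k]))
  }
  probs
}

#' Repair labels to the nearest graph-feasible labeling
#'
#' M/P runs are clamped into the admissible 18-25 nt range (trimmed at
#' the loop-distal end, or extended into adjacent F/N context), F runs
#' are truncated/extended to exactly 20 nt around the duplex, and short
#' L runs are widened at the expense of neighbouring positions. Emits a
#' warning describing each repair.
#'
#' @inheritParams validate_labels
#' @return repaired character label vector.
#' @export
repair_labels <- function(labels, arch = arch_config()) {
  probs <- validate_labels(labels, arch)
  if (!length(probs)) return(labels)
  warning("repairing infeasible labels: ", paste(probs, collapse = "; "))
  n <- length(labels)
  min_strand <- min(arch$skip_from) + 1L
  bounds <- list(M = c(min_strand, arch$n_mature),
                 P = c(min_strand, arch$n_passenger),
                 L = c(arch$n_loop, n), F = rep(arch$n_flank, 2L))
  duplexish <- c("M", "P", "L")
  fix_once <- function(labels) {
    r <- rle(labels)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      val <- r$values[k]
      if (val == "N") next
      lo <- bounds[[val]][1]; hi <- bounds[[val]][2]
      len <- r$lengths[k]
      if (len >= lo && len <= hi) next
      # adjust at the side facing away from the duplex so repairs do
      # not cascade into M/P/L runs
      nxt <- if (k < length(r$values)) r$values[k + 1L] else "N"
      prv <- if (k > 1L) r$values[k - 1L] else "N"
      at_end <- if (nxt %in% duplexish && !(prv %in% duplexish))
        "start" else "end"
      delta <- if (len > hi) len - hi else len - lo # + trim, - extend
      if (at_end == "end") {
        if (delta > 0L)
          labels[(ends[k] - delta + 1L):ends[k]] <- nxt
        else if (ends[k] < n)
          labels[(ends[k] + 1L):min(n, ends[k] - delta)] <- val
      } else {
        if (delta > 0L)
          labels[starts[k]:(starts[k] + delta - 1L)] <- prv
        else if (starts[k] > 1L)
          labels[max(1L, starts[k] + delta):(starts[k] - 1L)] <- val
      }
      return(labels) # one repair per pass; revalidate
    }
    labels
  }
  for (it in 1:20) {
    if (!length(validate_labels(labels, arch))) break
    new <- fix_once(labels)
    if (identical(new, labels)) break
    labels <- new
  }
  labels
}

.fb <- function(graph, params, symbols, labels = NULL, grad = FALSE,
                post = FALSE) {
  symbols <- unclass(symbols)
  storage.mode(symbols) <- "integer"
  lab <- if (is.null(labels)) integer(nrow(symbols)) else
    .label_codes[labels]
  .crf_fb_cpp(symbols, as.integer(lab),
              as.integer(.label_codes[graph$states$label]),
              .emission_weights(params),
              graph$edges$from, graph$edges$to,
              .transition_weights(params), grad, post)
}

#' Label-constrained conditional log-likelihood and its gradient
#'
#' `log P(y | x; m)` for one example: the log-partition function of the
#' label-constrained graph (only states whose label matches each
#' position) minus the log-partition function of the full graph. The
#' gradient is the difference of expected feature counts under the two
#' distributions, computed by forward-backward.
#'
#' @param params a [crf_params()].
#' @param example a [labeled_example()].
#' @param graph a [state_graph()].
#' @param gradient also compute the gradient.
#' @return list with `value` (<= 0) and, if requested, `gradient`.
#' @export
constrained_log_likelihood <- function(params, example, graph,
                                       gradient = TRUE) {
  stopifnot(inherits(example, "labeled_example"))
  con <- .fb(graph, params, example$symbols, example$labels,
             grad = gradient)
  if (!con$feasible)
    stop(sprintf(
      "labels admit no consistent path (first infeasible position: %d)",
      con$first_infeasible))
  full <- .fb(graph, params, example$symbols, grad = gradient)
  out <- list(value = con$log_z - full$log_z)
  if (gradient)
    out$gradient <- c(con$grad_w - full$grad_w,
                      con$grad_tr - full$grad_tr)
  out
}

#' Penalized training objective
#'
#' Sum of constrained log-likelihoods over the examples minus the
#' Gaussian prior `sum_j m_j^2 / (2c)`; larger `c` means weaker
#' shrinkage.
#'
#' @param params a [crf_params()].
#' @param examples list of [labeled_example()].
#' @param c positive penalty constant.
#' @param graph a [state_graph()].
#' @param gradient also compute the gradient.
#' @return list with `value` and, if requested, `gradient`.
#' @export
penalized_objective <- function(params, examples, c, graph,
                                gradient = TRUE) {
  stopifnot(c > 0)
  value <- -sum(params$m^2) / (2 * c)
  grad <- if (gradient) -params$m / c
  for (ex in examples) {
    ll <- constrained_log_likelihood(params, ex, graph, gradient)
    value <- value + ll$value
    if (gradient) grad <- grad + ll$gradient
  }
  out <- list(value = value)
  if (gradient) out$gradient <- grad
  out
}
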