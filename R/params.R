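#' Model parameters for a state graph
#'
#' The parameter vector `m` concatenates the per-state emission weight
#' tables (35 weights per state: alphabet sizes 5,5,5,5,5,6,4 over the 7
#' feature dimensions) with one transition weight per edge. All
#' parameters start at zero.
#'
#' @param graph a [state_graph()].
#' @param m optional numeric vector of length `K*35 + n_edges`.
#' @return an object of class `crf_params`.
#' @export
crf_params <- function(graph, m = NULL) {
  stopifnot(inherits(graph, "state_graph"))
  n_em <- graph$n_states * .n_emission_per_state
  J <- n_em + graph$n_edges
  if (is.null(m)) m <- numeric(J)
  if (length(m) != J) stop("parameter vector must have length ", J)
  if (!all(is.finite(m))) stop("parameters must be finite")
  structure(list(m = as.numeric(m), n_em = n_em, J = J),
            class = "crf_params")
}

#' @export
print.crf_params <- function(x, ...) {
  cat(sprintf("crf_params: %d emission + %d transition = %d parameters\n",
              x$n_em, x$J - x$n_em, x$J))
  invisible(x)
}

.emission_weights <- function(params) params$m[seq_len(params$n_em)]
.transition_weights <- function(params)
  params$m[seq.int(params$n_em + 1L, params$J)]

.symbol_index <- function(symbols, dims = seq_len(7L)) {
  # character symbols A..F -> integer index within each dimension
  idx <- match(symbols, LETTERS[1:6])
  if (anyNA(idx)) stop("unknown symbol: ",
                       paste(symbols[is.na(idx)], collapse = ", "))
  if (any(idx > .dim_alphabet_sizes[dims]))
    stop("symbol outside its dimension's alphabet")
  idx
}

#' Emission score of a state for a 7-symbol vector
#'
#' The emission function is log-linear: the score is the sum over the 7
#' dimensions of the weight assigned to the observed symbol,
#' `sum_d w^d_state(o_i^d)`.
#'
#' @param state state id.
#' @param symbol_vector character vector of 7 symbols (or integer
#'   indices within each dimension's alphabet).
#' @param params a [crf_params()].
#' @param graph the [state_graph()] the parameters belong to.
#' @return numeric score.
#' @export
emission_score <- function(state, symbol_vector, params, graph) {
  stopifnot(length(symbol_vector) == 7L, state >= 1L,
            state <= graph$n_states)
  idx <- if (is.character(symbol_vector))
    .symbol_index(symbol_vector) else as.integer(symbol_vector)
  if (any(idx < 1L | idx > .dim_alphabet_sizes))
    stop("symbol outside its dimension's alphabet")
  w <- params$m[(state - 1L) * .n_emission_per_state +
                  .emission_offsets + idx]
  sum(w)
}

.edge_param_id <- function(graph, params, from, to) {
  hit <- which(graph$edges$from == from & graph$edges$to == to)
  if (!length(hit)) return(NA_integer_)
  params$n_em + hit[1L]
}

#' Unnormalized CRF path score
#'
#' Sum of emission scores along the path plus transition weights of all
#' traversed edges, including the start and end anchor edges;
#' `exp(score)` is the path's unnormalized probability.
#'
#' @param state_path integer vector of emitting state ids.
#' @param symbols integer matrix `length(state_path)` x 7 of symbol
#'   indices (or a `symbol_sequence`).
#' @param params a [crf_params()].
#' @param graph a [state_graph()].
#' @return numeric score.
#' @export
path_score <- function(state_path, symbols, params, graph) {
  T_ <- length(state_path)
  symbols <- unclass(symbols)
  stopifnot(is.matrix(symbols), nrow(symbols) == T_, ncol(symbols) == 7L)
  steps <- cbind(from = c(0L, state_path),
                 to = c(state_path, graph$n_states + 1L))
  score <- 0
  for (s in seq_len(nrow(steps))) {
    pid <- .edge_param_id(graph, params, steps[s, 1], steps[s, 2])
    if (is.na(pid))
      stop(sprintf("illegal edge %d -> %d at step %d",
                   steps[s, 1], steps[s, 2], s))
    score <- score + params$m[pid]
  }
  for (t in seq_len(T_))
    score <- score + emission_score(state_path[t], symbols[t, ], params,
                                    graph)
  score
}

#' Serialize a model (graph + parameters + codec) to JSON
#'
#' The model file is self-contained: it carries the state graph, the
#' trained weights, and the quantile codec so a saved model can be used
#' for scanning without any training-time context.
#'
#' @param model a `crf_model` list with elements `graph`, `params`, and
#'   optionally `codec` and `meta`.
#' @param path output file.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model$graph, "state_graph"),
            inherits(model$params, "crf_params"))
  obj <- list(
    schema = "hairpinCRF-model-v1",
    states = model$graph$states,
    edges = model$graph$edges,
    s_mirna = model$graph$s_mirna,
    s_5end = model$graph$s_5end,
    m = model$params$m,
    codec = if (!is.null(model$codec)) unclass(model$codec),
    meta = model$meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a model written by [write_model()]
#' @param path model JSON file.
#' @return a `crf_model` list.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "hairpinCRF-model-v1"))
    stop("unrecognized model schema in ", path)
  states <- as.data.frame(obj$states)
  states$id <- as.integer(states$id)
  states$pos <- as.integer(states$pos)
  graph <- state_graph(states, as.data.frame(obj$edges),
                       obj$s_mirna, obj$s_5end)
  codec <- if (!is.null(obj$codec)) {
    cd <- obj$codec
    cd$boundaries <- as.matrix(cd$boundaries)
    structure(cd, class = "quantile_codec")
  }
  structure(list(graph = graph, params = crf_params(graph, obj$m),
                 codec = codec, meta = obj$meta),
            class = "crf_model")
}

#' @export
print.crf_model <- function(x, ...) {
  cat("crf_model\n")
  print(x$graph)
  print(x$params)
  invisible(x)
}
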