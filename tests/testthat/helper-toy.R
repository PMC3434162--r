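# shared fixtures built in code

# a tiny 3-state graph (Mature, Loop, NonMiRNA) rich enough to exercise
# constrained likelihoods; all states inter-connected, start on M or N,
# end from N or L
toy_graph <- function() {
  st <- data.frame(id = 1:3, submodel = c("A", "B", "C"),
                   role = c("Mature", "Loop", "NonMiRNA"),
                   label = c("M", "L", "N"), pos = 1L,
                   stringsAsFactors = FALSE)
  ed <- data.frame(from = c(0, 0, 1, 1, 2, 2, 3, 3, 1, 3),
                   to   = c(1, 3, 2, 1, 3, 2, 3, 4, 4, 1))
  state_graph(st, ed, s_mirna = c(1, 2), s_5end = 1)
}

# a random small graph over n_states <= 6 with random label assignment;
# always contains a start edge, an end edge, and a connected chain
random_small_graph <- function(n_states, seed) {
  set.seed(seed)
  labs <- sample(c("M", "P", "L", "F", "N"), n_states, replace = TRUE)
  st <- data.frame(id = seq_len(n_states),
                   submodel = paste0("S", seq_len(n_states)),
                   role = "NonMiRNA", label = labs, pos = 1L,
                   stringsAsFactors = FALSE)
  ed <- data.frame(from = c(0, seq_len(n_states - 1), n_states),
                   to = c(1, seq_len(n_states - 1) + 1, n_states + 1))
  # self-loops on the first and last state keep every path length
  # >= n_states feasible
  ed <- rbind(ed, data.frame(from = c(1, n_states), to = c(1, n_states)))
  # random extra edges (may include self-loops and back edges)
  extra_from <- sample(n_states, n_states + 2, replace = TRUE)
  extra_to <- sample(n_states, n_states + 2, replace = TRUE)
  ed <- unique(rbind(ed, data.frame(from = extra_from, to = extra_to)))
  # a second start and end edge for variety
  ed <- unique(rbind(ed, data.frame(from = c(0, sample(n_states, 1)),
                                    to = c(sample(n_states, 1),
                                           n_states + 1))))
  state_graph(st, ed, s_mirna = which(labs != "N"),
              s_5end = which(labs == "M")[1] %||% integer(),
              validate = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a)))
  b else a

random_symbols <- function(T_, seed) {
  set.seed(seed)
  m <- sapply(c(5, 5, 5, 5, 5, 6, 4), function(k)
    sample.int(k, T_, replace = TRUE))
  structure(matrix(as.integer(m), T_, 7), class = "symbol_sequence")
}

# brute-force path statistics for a graph + parameters
enum_path_stats <- function(graph, params, symbols, labels = NULL) {
  T_ <- nrow(unclass(symbols))
  paths <- enumerate_paths(graph, T_)
  if (!is.null(labels)) {
    lab <- graph$states$label
    paths <- Filter(function(p) all(lab[p] == labels), paths)
  }
  if (!length(paths)) return(list(log_z = -Inf, post = NULL))
  scores <- vapply(paths, function(p)
    path_score(p, symbols, params, graph), numeric(1))
  mx <- max(scores)
  w <- exp(scores - mx)
  post <- matrix(0, T_, graph$n_states)
  for (k in seq_along(paths))
    for (t in seq_len(T_))
      post[t, paths[[k]][t]] <- post[t, paths[[k]][t]] + w[k]
  list(log_z = mx + log(sum(w)), post = post / sum(w), n = length(paths))
}

# sample a label path y ~ P(y | x; m) exactly, via path enumeration
sample_path <- function(graph, params, symbols, seed) {
  set.seed(seed)
  T_ <- nrow(unclass(symbols))
  paths <- enumerate_paths(graph, T_)
  scores <- vapply(paths, function(p)
    path_score(p, symbols, params, graph), numeric(1))
  w <- exp(scores - max(scores))
  paths[[sample.int(length(paths), 1, prob = w)]]
}
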