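#' Architecture configuration for the hairpin state graph
#'
#' Defaults reproduce the 12-sub-model topology: 4 Mature and 2 Passenger
#' sub-models of 25 linearly connected states with skip edges admitting
#' strand lengths of 18-25 nt, 3 Loop sub-models of 8 self-looped chain
#' states (minimum loop traversal 8 nt), 2 Flanking sub-models of 20
#' linearly connected states (exactly 20 nt), and a single self-looping
#' Non-miRNA state. Three paths through the duplex encode the three
#' possible mature-strand locations: 5'-arm, 3'-arm, or both arms.
#'
#' @param n_mature,n_passenger,n_loop,n_flank states per sub-model.
#' @param skip_from chain states with a skip edge directly to the last
#'   Mature/Passenger state; defaults admit segment lengths 18-25 nt.
#' @return an object of class `arch_config`.
#' @export
arch_config <- function(n_mature = 25L, n_passenger = 25L, n_loop = 8L,
                        n_flank = 20L, skip_from = 17L:24L) {
  structure(list(n_mature = as.integer(n_mature),
                 n_passenger = as.integer(n_passenger),
                 n_loop = as.integer(n_loop),
                 n_flank = as.integer(n_flank),
                 skip_from = as.integer(skip_from)),
            class = "arch_config")
}

#' Low-level state graph constructor
#'
#' @param states data.frame with columns `id` (1..K), `submodel`, `role`
#'   (one of Mature, Passenger, Loop, Flanking, NonMiRNA), `label`
#'   (M/P/L/F/N) and `pos` (position index within the sub-model).
#' @param edges data.frame with columns `from`, `to`; state 0 is the
#'   start anchor, K+1 the end anchor. Each edge carries its own
#'   transition parameter.
#' @param s_mirna,s_5end state-id sets defining the hairpin and
#'   mature-5'-end posteriors.
#' @param validate check reachability/co-reachability of every state.
#' @return an object of class `state_graph`.
#' @export
state_graph <- function(states, edges, s_mirna, s_5end, validate = TRUE) {
  stopifnot(all(c("id", "submodel", "role", "label", "pos") %in%
                  names(states)),
            all(c("from", "to") %in% names(edges)))
  K <- nrow(states)
  stopifnot(identical(states$id, seq_len(K)))
  if (!all(states$label %in% names(.label_codes)))
    stop("state labels must be in {M,P,L,F,N}")
  edges <- data.frame(from = as.integer(edges$from),
                      to = as.integer(edges$to))
  if (any(edges$from < 0L | edges$from > K) ||
      any(edges$to < 1L | edges$to > K + 1L))
    stop("edge endpoints outside [0, K+1]")
  if (anyDuplicated(edges)) stop("duplicate edges")
  g <- structure(list(states = states, edges = edges,
                      s_mirna = as.integer(s_mirna),
                      s_5end = as.integer(s_5end),
                      n_states = K, n_edges = nrow(edges)),
                 class = "state_graph")
  if (validate) .validate_graph(g)
  g
}

.validate_graph <- function(g) {
  K <- g$n_states
  # forward reachability from start (0), backward from end (K+1)
  reach <- function(from0, ef, et) {
    seen <- logical(K + 2L)
    seen[from0 + 1L] <- TRUE
    repeat {
      new <- unique(et[seen[ef + 1L] & !seen[et + 1L]])
      if (!length(new)) break
      seen[new + 1L] <- TRUE
    }
    seen
  }
  fwd <- reach(0L, g$edges$from, g$edges$to)
  bwd <- reach(K + 1L, g$edges$to, g$edges$from)
  bad <- which(!(fwd[seq_len(K) + 1L] & bwd[seq_len(K) + 1L]))
  if (length(bad))
    stop("states unreachable from start or end: ",
         paste(bad, collapse = ", "))
  invisible(g)
}

#' Build the default hairpin CRF topology
#'
#' Start -> Non-miRNA (self-loop) -> left Flanking -> one of three duplex
#' paths (Mature-Loop-Passenger, Passenger-Loop-Mature,
#' Mature-Loop-Mature) -> right Flanking -> Non-miRNA -> end. `S_5end`
#' is the set of entry states of the four Mature sub-models; `S_mirna`
#' is every state except Non-miRNA.
#'
#' @param arch an [arch_config()].
#' @return a [state_graph()].
#' @export
build_state_graph <- function(arch = arch_config()) {
  stopifnot(inherits(arch, "arch_config"))
  states <- data.frame(id = integer(), submodel = character(),
                       role = character(), label = character(),
                       pos = integer(), stringsAsFactors = FALSE)
  edges <- data.frame(from = integer(), to = integer())
  add_states <- function(submodel, role, label, n) {
    id0 <- nrow(states)
    states <<- rbind(states, data.frame(
      id = id0 + seq_len(n), submodel = submodel, role = role,
      label = label, pos = seq_len(n), stringsAsFactors = FALSE))
    id0 + seq_len(n)
  }
  add_edges <- function(from, to) {
    edges <<- rbind(edges, data.frame(from = from, to = to))
  }
  chain <- function(ids) if (length(ids) > 1L)
    add_edges(ids[-length(ids)], ids[-1L])
  strand <- function(submodel, role, label, n) {
    ids <- add_states(submodel, role, label, n)
    chain(ids)
    skip <- setdiff(arch$skip_from, n - 1L) # chain edge already present
    skip <- skip[skip >= 1L & skip < n]
    if (length(skip)) add_edges(ids[skip], ids[n])
    ids
  }
  loop_sm <- function(submodel) {
    ids <- add_states(submodel, "Loop", "L", arch$n_loop)
    chain(ids)
    add_edges(ids, ids) # self-loops on every loop state
    ids
  }

  nonmi <- add_states("NonMiRNA", "NonMiRNA", "N", 1L)
  add_edges(nonmi, nonmi)
  flank_l <- add_states("Flanking_L", "Flanking", "F", arch$n_flank)
  chain(flank_l)
  m_a <- strand("Mature_5arm", "Mature", "M", arch$n_mature)
  l_1 <- loop_sm("Loop_1")
  p_a <- strand("Passenger_3arm", "Passenger", "P", arch$n_passenger)
  p_b <- strand("Passenger_5arm", "Passenger", "P", arch$n_passenger)
  l_2 <- loop_sm("Loop_2")
  m_b <- strand("Mature_3arm", "Mature", "M", arch$n_mature)
  m_c <- strand("Mature_both5", "Mature", "M", arch$n_mature)
  l_3 <- loop_sm("Loop_3")
  m_d <- strand("Mature_both3", "Mature", "M", arch$n_mature)
  flank_r <- add_states("Flanking_R", "Flanking", "F", arch$n_flank)
  chain(flank_r)

  start <- 0L; end <- nrow(states) + 1L
  add_edges(start, nonmi)
  add_edges(nonmi, flank_l[1])
  last_fl <- flank_l[arch$n_flank]
  add_edges(rep(last_fl, 3L), c(m_a[1], p_b[1], m_c[1]))
  nm <- arch$n_mature; np <- arch$n_passenger; nl <- arch$n_loop
  add_edges(m_a[nm], l_1[1]); add_edges(l_1[nl], p_a[1])
  add_edges(p_b[np], l_2[1]); add_edges(l_2[nl], m_b[1])
  add_edges(m_c[nm], l_3[1]); add_edges(l_3[nl], m_d[1])
  add_edges(c(p_a[np], m_b[nm], m_d[nm]), rep(flank_r[1], 3L))
  add_edges(flank_r[arch$n_flank], nonmi)
  add_edges(nonmi, end)

  state_graph(states, edges,
              s_mirna = states$id[states$label != "N"],
              s_5end = c(m_a[1], m_b[1], m_c[1], m_d[1]))
}

#' @export
print.state_graph <- function(x, ...) {
  cat(sprintf(
    "state_graph: %d sub-models, %d emitting states, %d edges\n",
    length(unique(x$states$submodel)), x$n_states, x$n_edges))
  cat(sprintf("  |S_mirna| = %d, |S_5end| = %d\n",
              length(x$s_mirna), length(x$s_5end)))
  invisible(x)
}

#' Enumerate all start-to-end state paths of a given length
#'
#' Exhaustive enumeration over the graph; exponential, intended only as
#' an independent oracle for validating forward-backward on tiny graphs.
#'
#' @param graph a [state_graph()].
#' @param len number of emitting positions.
#' @param max_paths refusal limit.
#' @return a list of integer state-id vectors, each of length `len`.
#' @export
enumerate_paths <- function(graph, len, max_paths = 2e5) {
  K <- graph$n_states
  out_edges <- split(graph$edges$to, graph$edges$from)
  paths <- list()
  walk <- function(state, path) {
    if (length(paths) > max_paths)
      stop("too many paths to enumerate (limit ", max_paths, ")")
    if (length(path) == len) {
      if ((K + 1L) %in% out_edges[[as.character(state)]])
        paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (nxt in out_edges[[as.character(state)]]) {
      if (nxt <= K) walk(nxt, c(path, nxt))
    }
  }
  for (first in out_edges[["0"]]) {
    if (first <= K) walk(first, first)
  }
  paths
}
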