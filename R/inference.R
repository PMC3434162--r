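#' Per-position per-state posterior probabilities
#'
#' Exact CRF posteriors `p_{i,k}` by forward-backward; rows sum to 1.
#'
#' @param params a [crf_params()].
#' @param graph a [state_graph()].
#' @param symbols a `symbol_sequence` (integer matrix T x 7).
#' @return numeric matrix T x K of posteriors.
#' @export
forward_backward <- function(params, graph, symbols) {
  symbols <- unclass(symbols)
  if (is.null(dim(symbols)) || nrow(symbols) == 0L)
    return(matrix(numeric(), 0L, graph$n_states))
  res <- .fb(graph, params, symbols, post = TRUE)
  if (!res$feasible) stop("no legal path through the graph")
  res$posteriors
}

#' Hairpin probability track
#'
#' `P^mi_i = sum_{k in S_mirna} p_{i,k}`: the posterior probability that
#' position i lies in a hairpin (any Flanking, Mature, Passenger or Loop
#' state).
#'
#' @param posteriors matrix from [forward_backward()].
#' @param graph a [state_graph()].
#' @return numeric vector.
#' @export
hairpin_probability <- function(posteriors, graph) {
  if (nrow(posteriors) == 0L) return(numeric())
  rowSums(posteriors[, graph$s_mirna, drop = FALSE])
}

#' Mature 5'-end probability track
#'
#' `P^5end_i = sum_{k in S_5end} p_{i,k}`: the posterior probability
#' that position i is the 5'-end of a mature miRNA (entry state of any
#' Mature sub-model).
#'
#' @inheritParams hairpin_probability
#' @return numeric vector.
#' @export
mature_5end_probability <- function(posteriors, graph) {
  if (nrow(posteriors) == 0L) return(numeric())
  rowSums(posteriors[, graph$s_5end, drop = FALSE])
}

#' Call hairpin segments from a probability track
#'
#' Maximal runs of positions with `P^mi > T`; runs shorter than
#' `min_length` or of `max_length` or more are discarded.
#'
#' @param p_mi numeric probability track.
#' @param threshold probability threshold `T` in (0, 1).
#' @param min_length minimal segment length kept (nt).
#' @param max_length segments of this length or more are discarded.
#' @return data.frame with 1-based inclusive `start`, `end` and `score`
#'   (maximal `P^mi` within the segment).
#' @export
call_hairpins <- function(p_mi, threshold, min_length = 80L,
                          max_length = 150L) {
  stopifnot(threshold > 0, threshold < 1)
  above <- p_mi > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length & r$lengths < max_length
  data.frame(start = starts[keep], end = ends[keep],
             score = vapply(which(keep), function(k)
               max(p_mi[starts[k]:ends[k]]), numeric(1)))
}

#' Call mature 5'-end positions
#'
#' All positions with `P^5end > T`; when `gate` is TRUE, restricted to
#' positions inside called hairpin segments.
#'
#' @param p_5end numeric probability track.
#' @param threshold probability threshold `T` in (0, 1).
#' @param segments optional data.frame from [call_hairpins()].
#' @param gate restrict calls to `segments`.
#' @return data.frame with `pos` (1-based) and `p`.
#' @export
call_5ends <- function(p_5end, threshold, segments = NULL, gate = TRUE) {
  stopifnot(threshold > 0, threshold <= 1)
  pos <- which(p_5end > threshold)
  if (gate) {
    if (is.null(segments))
      stop("gating requested but no segments supplied")
    inside <- rep(FALSE, length(p_5end))
    for (s in seq_len(nrow(segments)))
      inside[segments$start[s]:segments$end[s]] <- TRUE
    pos <- pos[inside[pos]]
  }
  data.frame(pos = pos, p = p_5end[pos])
}

.revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gsub("U", "T", toupper(sequence)))))
}

.scan_one_strand <- function(model, sequence, tracks, window, overlap,
                             fold_cfg, pair_threshold) {
  graph <- model$graph
  n <- nchar(sequence)
  step <- window - overlap
  starts <- if (n <= window) 1L else {
    s <- seq.int(1L, n - window, by = step)
    if (tail(s, 1L) + window - 1L < n) s <- c(s, n - window + 1L)
    s
  }
  # fold and featurize the whole strand once; only the CRF decoding is
  # windowed, so stitched posteriors differ from an unwindowed run only
  # through the decaying boundary effect of the non-miRNA anchoring
  bpm <- compute_pair_probabilities(sequence, fold_cfg)
  raw <- build_raw_features(sequence, tracks, bpm, pair_threshold)
  sym_all <- unclass(encode_features(raw, model$codec))
  p_mi <- numeric(n); p_5 <- numeric(n)
  best <- rep(-1, n) # distance-to-edge of the window each value came from
  for (ws in starts) {
    we <- min(n, ws + window - 1L)
    len <- we - ws + 1L
    sym <- structure(sym_all[ws:we, , drop = FALSE],
                     class = "symbol_sequence")
    post <- forward_backward(model$params, graph, sym)
    wmi <- hairpin_probability(post, graph)
    w5 <- mature_5end_probability(post, graph)
    local <- seq_len(len)
    dist <- pmin(local - 1L, len - local)
    # sequence ends are true boundaries, not window artifacts
    if (ws == 1L) dist <- pmax(dist, local - 1L + window)
    if (we == n) dist <- pmax(dist, len - local + window)
    g <- ws + local - 1L
    take <- dist > best[g]
    gi <- g[take]
    p_mi[gi] <- wmi[local[take]]
    p_5[gi] <- w5[local[take]]
    best[gi] <- dist[take]
  }
  list(p_mi = p_mi, p_5end = p_5)
}

#' Scan a genomic sequence for miRNA hairpins
#'
#' Folds, featurizes and decodes the sequence in overlapping windows;
#' posterior tracks are stitched so that every position takes its value
#' from the window in which it is farthest from a window edge (CRF
#' posteriors near window boundaries are biased by the forced non-miRNA
#' anchoring). Hairpin segments and mature 5'-end calls are made on the
#' stitched tracks.
#'
#' @param model a `crf_model` (graph + params + codec), e.g. from
#'   [read_model()] or assembled after [select_penalty()].
#' @param sequence genomic sequence string.
#' @param tracks a [conservation_tracks()] covering the sequence.
#' @param window,overlap scan window size and overlap (nt; both >= 300,
#'   window > overlap).
#' @param t_hairpin,t_5end probability thresholds for segment and
#'   5'-end calling (default equal).
#' @param fold_cfg a [fold_config()].
#' @param pair_threshold BPP threshold for the base-pair distance.
#' @param both_strands also scan the reverse complement (tracks are
#'   strand-symmetric and reused reversed); coordinates are mapped back
#'   to the forward strand.
#' @param gate restrict 5'-end calls to called segments.
#' @return an object of class `prediction`: list with `segments`
#'   (start, end, score, strand; 1-based inclusive), `five_prime`
#'   (pos, p, strand), and the stitched `p_mi` / `p_5end` tracks
#'   (forward strand).
#' @export
scan_genome <- function(model, sequence, tracks, window = 2000L,
                        overlap = 400L, t_hairpin = 0.5,
                        t_5end = t_hairpin,
                        fold_cfg = fold_config(),
                        pair_threshold = 0.5, both_strands = FALSE,
                        gate = TRUE) {
  window <- as.integer(window); overlap <- as.integer(overlap)
  if (window < 300L || overlap < 300L)
    stop("window and overlap must both be >= 300 nt")
  if (window <= overlap) stop("window must exceed overlap")
  n <- nchar(sequence)
  stopifnot(inherits(tracks, "conservation_tracks"), tracks$length == n)

  fwd <- .scan_one_strand(model, sequence, tracks, window, overlap,
                          fold_cfg, pair_threshold)
  segs <- call_hairpins(fwd$p_mi, t_hairpin)
  if (nrow(segs)) segs$strand <- "+"
  else segs <- cbind(segs, data.frame(strand = character()))
  fps <- call_5ends(fwd$p_5end, t_5end, segs, gate)
  if (nrow(fps)) fps$strand <- "+"
  else fps <- cbind(fps, data.frame(strand = character()))

  rev_tracks <- NULL
  if (both_strands) {
    rseq <- .revcomp(sequence)
    rtr <- conservation_tracks(rev(tracks$phastcons),
                               rev(tracks$phylop))
    rev_scan <- .scan_one_strand(model, rseq, rtr, window, overlap,
                                 fold_cfg, pair_threshold)
    rsegs <- call_hairpins(rev_scan$p_mi, t_hairpin)
    rfps <- call_5ends(rev_scan$p_5end, t_5end, rsegs, gate)
    if (nrow(rsegs)) {
      rsegs <- data.frame(start = n - rsegs$end + 1L,
                          end = n - rsegs$start + 1L,
                          score = rsegs$score, strand = "-")
      segs <- rbind(segs, rsegs)
    }
    if (nrow(rfps)) {
      rfps <- data.frame(pos = n - rfps$pos + 1L, p = rfps$p,
                         strand = "-")
      fps <- rbind(fps, rfps)
    }
    rev_tracks <- rev_scan
  }
  structure(list(segments = segs, five_prime = fps, p_mi = fwd$p_mi,
                 p_5end = fwd$p_5end, reverse = rev_tracks,
                 t_hairpin = t_hairpin, t_5end = t_5end),
            class = "prediction")
}

#' @export
print.prediction <- function(x, ...) {
  cat(sprintf(
    "prediction: %d hairpin segment(s), %d mature 5'-end call(s) (T = %g/%g)\n",
    nrow(x$segments), nrow(x$five_prime), x$t_hairpin, x$t_5end))
  invisible(x)
}
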