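#' Folding configuration
#'
#' Parameters for the windowed partition-function folding. The default
#' energy model scores each base pair by type (GC -3, AU -2, GU -1, in
#' units where `temperature_scale = 1`); structures are Boltzmann-weighted
#' by the sum of their pair scores. Pairs spanning more than `max_span`
#' nucleotides are forbidden, which is what makes genome-scale folding
#' linear in sequence length.
#'
#' @param max_span maximal allowed base-pair span `j - i` in nt.
#' @param min_loop minimal number of unpaired nt enclosed by a pair
#'   (steric hairpin-loop minimum).
#' @param energy_model identifier of the pair-scoring scheme; only
#'   `"simple"` is built in. Matrices from an external folding engine can
#'   be supplied directly via [base_pair_matrix()].
#' @param temperature_scale positive Boltzmann scale factor.
#' @param pair_scores named vector with elements `GC`, `AU`, `GU` giving
#'   the score of each pair type (more negative = more stable).
#' @return an object of class `fold_config`.
#' @export
fold_config <- function(max_span = 120L, min_loop = 3L,
                        energy_model = "simple", temperature_scale = 1,
                        pair_scores = c(GC = -3, AU = -2, GU = -1)) {
  max_span <- as.integer(max_span)
  min_loop <- as.integer(min_loop)
  stopifnot(is.finite(max_span), is.finite(min_loop))
  if (min_loop < 0L) stop("min_loop must be >= 0")
  if (max_span < min_loop + 2L) stop("max_span must be >= min_loop + 2")
  if (!is.numeric(temperature_scale) || temperature_scale <= 0)
    stop("temperature_scale must be > 0")
  if (!identical(energy_model, "simple"))
    stop("unknown energy_model: ", energy_model)
  if (!all(c("GC", "AU", "GU") %in% names(pair_scores)))
    stop("pair_scores must name GC, AU and GU")
  structure(list(max_span = max_span, min_loop = min_loop,
                 energy_model = energy_model,
                 temperature_scale = temperature_scale,
                 pair_scores = pair_scores),
            class = "fold_config")
}

#' Base-pair probability matrix
#'
#' Sparse container for pair probabilities p_ij (i < j). Entries absent
#' from the triplet lists are implicitly zero. This constructor is also
#' the hook for plugging in matrices computed by an external folding
#' engine: supply its (i, j, p) triplets and the sequence length.
#'
#' @param length sequence length in nt.
#' @param i,j 1-based paired positions, `i < j`.
#' @param p pair probabilities in `[0, 1]`.
#' @param log_z log partition function, if known.
#' @param max_span span constraint the matrix was computed under.
#' @return an object of class `base_pair_matrix`.
#' @export
base_pair_matrix <- function(length, i = integer(), j = integer(),
                             p = numeric(), log_z = NA_real_,
                             max_span = NA_integer_) {
  length <- as.integer(length)
  i <- as.integer(i); j <- as.integer(j); p <- as.numeric(p)
  stopifnot(length(i) == length(j), length(i) == length(p))
  if (any(i >= j)) stop("base_pair_matrix requires i < j")
  if (length(i) && (min(i) < 1L || max(j) > length))
    stop("pair indices outside [1, length]")
  if (any(p < 0 | p > 1 + 1e-9)) stop("pair probabilities must lie in [0, 1]")
  structure(list(length = length, i = i, j = j, p = pmin(p, 1),
                 log_z = log_z, max_span = max_span),
            class = "base_pair_matrix")
}

#' @export
print.base_pair_matrix <- function(x, ...) {
  cat(sprintf("base_pair_matrix: %d nt, %d pairs with p > 0 (max_span %s)\n",
              x$length, length(x$i),
              ifelse(is.na(x$max_span), "unconstrained", x$max_span)))
  invisible(x)
}

#' @export
as.matrix.base_pair_matrix <- function(x, ...) {
  m <- matrix(0, x$length, x$length)
  if (length(x$i)) {
    m[cbind(x$i, x$j)] <- x$p
    m[cbind(x$j, x$i)] <- x$p
  }
  m
}

.encode_nucleotides <- function(sequence, what = "sequence") {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  chars[chars == "T"] <- "U"
  codes <- match(chars, c("A", "C", "G", "U", "N")) - 1L
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    stop(sprintf("invalid character '%s' in %s at position %d",
                 chars[bad], what, bad))
  }
  codes
}

#' Compute base-pair probabilities by dynamic programming
#'
#' Exact partition-function pair probabilities under the configured
#' pair-additive energy model, with every pair forced to span at most
#' `config$max_span` nt and to enclose at least `config$min_loop`
#' unpaired nt. `T` is read as `U`; `N` never pairs.
#'
#' @param sequence RNA/DNA string over `A,C,G,U/T,N`.
#' @param config a [fold_config()].
#' @param prune probabilities at or below this value are not stored
#'   (sparsity control; set to 0 to keep every structurally possible
#'   pair).
#' @return a [base_pair_matrix()].
#' @export
compute_pair_probabilities <- function(sequence, config = fold_config(),
                                       prune = 1e-12) {
  stopifnot(inherits(config, "fold_config"))
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single string")
  if (nchar(sequence) == 0L)
    return(base_pair_matrix(0L, max_span = config$max_span))
  codes <- .encode_nucleotides(sequence)
  res <- .fold_bpp_cpp(codes, config$max_span, config$min_loop,
                       config$temperature_scale,
                       config$pair_scores[["GC"]],
                       config$pair_scores[["AU"]],
                       config$pair_scores[["GU"]], prune)
  base_pair_matrix(length(codes), res$i, res$j, res$p,
                   log_z = res$log_z, max_span = config$max_span)
}

#' Exhaustive-enumeration pair probabilities (test oracle)
#'
#' Enumerates every pseudoknot-free structure compatible with the
#' min-loop and max-span constraints, Boltzmann-weights them, and returns
#' exact pair probabilities. Exponential in sequence length; intended
#' only for validating the dynamic program on short sequences.
#'
#' @inheritParams compute_pair_probabilities
#' @param max_length refuse sequences longer than this.
#' @return a [base_pair_matrix()] with attribute `log_z`.
#' @export
enumerate_pair_probabilities <- function(sequence, config = fold_config(),
                                         max_length = 20L) {
  stopifnot(inherits(config, "fold_config"))
  n <- nchar(sequence)
  if (n > max_length)
    stop(sprintf("enumeration is exponential; refusing length %d (limit %d)",
                 n, max_length))
  if (n == 0L) return(base_pair_matrix(0L, max_span = config$max_span))
  codes <- .encode_nucleotides(sequence)
  sc <- config$pair_scores
  pair_score <- function(a, b) {
    # codes: 0=A 1=C 2=G 3=U 4=N
    key <- paste(sort(c(a, b)), collapse = "")
    switch(key, "12" = sc[["GC"]], "03" = sc[["AU"]], "23" = sc[["GU"]],
           NA_real_)
  }
  legal <- function(i, j) {
    j - i <= config$max_span && j - i - 1 >= config$min_loop &&
      !is.na(pair_score(codes[i], codes[j]))
  }
  # enumerate structures on [i, j] as lists of pair index matrices
  memo <- new.env(parent = emptyenv())
  structures <- function(i, j) {
    if (i >= j) return(list(matrix(integer(), ncol = 2)))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    # decompose on position i: unpaired, or paired with k
    out <- structures(i + 1L, j)
    for (k in seq.int(i + 1L, j)) {
      if (!legal(i, k)) next
      inner <- structures(i + 1L, k - 1L)
      outer <- structures(k + 1L, j)
      for (a in inner) for (b in outer)
        out[[length(out) + 1L]] <- rbind(matrix(c(i, k), ncol = 2), a, b)
    }
    memo[[key]] <- out
    out
  }
  structs <- structures(1L, n)
  lweights <- vapply(structs, function(s) {
    if (nrow(s) == 0L) return(0)
    -sum(vapply(seq_len(nrow(s)),
                function(r) pair_score(codes[s[r, 1]], codes[s[r, 2]]),
                numeric(1))) / config$temperature_scale
  }, numeric(1))
  mx <- max(lweights)
  w <- exp(lweights - mx)
  z <- sum(w)
  pm <- matrix(0, n, n)
  for (s in seq_along(structs)) {
    st <- structs[[s]]
    if (nrow(st)) pm[st] <- pm[st] + w[s]
  }
  pm <- pm / z
  idx <- which(pm > 0, arr.ind = TRUE)
  base_pair_matrix(n, idx[, 1], idx[, 2], pm[idx],
                   log_z = mx + log(z), max_span = config$max_span)
}

#' Per-position base-pair potential and distance
#'
#' For every position i, the base-pair potential `BPP_i` is the maximum
#' pair probability over all partners j (on either side), and the
#' base-pair distance `BPD_i` is the signed offset `j* - i` to the
#' maximizing partner, or `-Inf` when `BPP_i` falls below
#' `pair_threshold` (position considered unpaired).
#'
#' @param bpm a [base_pair_matrix()].
#' @param pair_threshold minimum BPP for a position to count as paired.
#' @return a list with numeric vectors `bpp` and `bpd`.
#' @export
pairing_profile <- function(bpm, pair_threshold = 0.5) {
  stopifnot(inherits(bpm, "base_pair_matrix"))
  n <- bpm$length
  bpp <- numeric(n)
  bpd <- rep(-Inf, n)
  if (length(bpm$i)) {
    pos <- c(bpm$i, bpm$j)
    partner <- c(bpm$j, bpm$i)
    p <- c(bpm$p, bpm$p)
    ord <- order(pos, -p)
    pos <- pos[ord]; partner <- partner[ord]; p <- p[ord]
    first <- !duplicated(pos)
    bpp[pos[first]] <- p[first]
    bpd[pos[first]] <- partner[first] - pos[first]
  }
  bpd[bpp < pair_threshold] <- -Inf
  list(bpp = bpp, bpd = bpd)
}
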