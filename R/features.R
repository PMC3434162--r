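#' Per-base conservation tracks
#'
#' @param phastcons numeric vector in `[0,1]` (NA = missing), or NULL if
#'   the whole track is unavailable.
#' @param phylop numeric vector (NA = missing), or NULL.
#' @param length sequence length; required if both tracks are NULL.
#' @return an object of class `conservation_tracks`.
#' @export
conservation_tracks <- function(phastcons = NULL, phylop = NULL,
                                length = NULL) {
  n <- length %||% length(phastcons) %||% length(phylop)
  if (is.null(n) || n == 0L && is.null(length))
    stop("cannot determine track length")
  n <- as.integer(n)
  if (is.null(phastcons)) {
    warning("phastcons track missing; substituting 0")
    phastcons <- numeric(n)
  }
  if (is.null(phylop)) {
    warning("phylop track missing; substituting 0")
    phylop <- numeric(n)
  }
  if (length(phastcons) != n || length(phylop) != n)
    stop("track lengths differ from sequence length")
  ok <- !is.na(phastcons)
  if (any(phastcons[ok] < 0 | phastcons[ok] > 1))
    stop("phastcons values must lie in [0, 1]")
  structure(list(phastcons = as.numeric(phastcons),
                 phylop = as.numeric(phylop), length = n),
            class = "conservation_tracks")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fill_nearest <- function(x) {
  # replace NAs by the nearest defined value (ties -> left neighbour)
  ok <- which(!is.na(x))
  if (!length(ok)) return(rep(0, length(x)))
  if (length(ok) == length(x)) return(x)
  idx <- seq_along(x)
  left <- findInterval(idx, ok)
  left_pos <- ifelse(left >= 1L, ok[pmax(left, 1L)], NA_integer_)
  right_pos <- ok[pmin(left + 1L, length(ok))]
  use_right <- is.na(left_pos) |
    (abs(right_pos - idx) < abs(idx - left_pos))
  pick <- ifelse(use_right, right_pos, left_pos)
  x[idx] <- x[pick]
  x
}

#' Build raw 7-dimensional feature vectors
#'
#' For each position i: d1 = PhastCons(i), d2 = PhastCons(i-20),
#' d3 = PhastCons(i+20), d4 = PhyloP(i), d5 = base-pair potential
#' (max_j p_ij), d6 = base-pair distance (signed offset to the
#' maximizing partner, `-Inf` if d5 < `pair_threshold`), d7 = the
#' nucleotide. Out-of-range shifts for d2/d3 clamp to the nearest
#' defined position; missing track values are filled from the nearest
#' defined neighbour.
#'
#' @param sequence nucleotide string.
#' @param tracks a [conservation_tracks()].
#' @param bpm a [base_pair_matrix()] for the same sequence.
#' @param pair_threshold BPP below which a position counts as unpaired.
#' @param offset genomic start coordinate (0-based) of position 1.
#' @return an object of class `raw_features`: a data.frame with columns
#'   `d1..d6` (numeric; only d6 may be `-Inf`) and `d7` (character),
#'   with attributes `offset` and `n_positions` (indices holding `N`).
#' @export
build_raw_features <- function(sequence, tracks, bpm,
                               pair_threshold = 0.5, offset = 0L) {
  stopifnot(inherits(tracks, "conservation_tracks"),
            inherits(bpm, "base_pair_matrix"))
  n <- nchar(sequence)
  if (tracks$length != n || bpm$length != n)
    stop(sprintf(
      "coordinate mismatch: sequence %d nt, tracks %d, matrix %d",
      n, tracks$length, bpm$length))
  pc <- .fill_nearest(tracks$phastcons)
  pp <- .fill_nearest(tracks$phylop)
  i <- seq_len(n)
  clamp <- function(k) pmin(pmax(k, 1L), n)
  prof <- pairing_profile(bpm, pair_threshold)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  chars[chars == "T"] <- "U"
  bad <- which(!chars %in% c("A", "U", "G", "C", "N"))
  if (length(bad))
    stop(sprintf("invalid nucleotide '%s' at position %d", chars[bad[1]],
                 bad[1]))
  out <- data.frame(d1 = pc[i], d2 = pc[clamp(i - 20L)],
                    d3 = pc[clamp(i + 20L)], d4 = pp[i],
                    d5 = prof$bpp, d6 = prof$bpd, d7 = chars,
                    stringsAsFactors = FALSE)
  structure(out, offset = as.integer(offset),
            n_positions = which(chars == "N"), class = c("raw_features",
                                                         "data.frame"))
}

#' Fit the per-dimension quantile codec
#'
#' Boundaries at the 20/40/60/80th percentiles (nearest-rank convention)
#' of the supplied finite training values for dimensions 1-6. Values of
#' `-Inf` in dimension 6 are excluded from the percentile computation
#' and map to symbol "F" at encoding time. A boundary value belongs to
#' the lower symbol.
#'
#' @param training_values list of 6 numeric vectors (raw values of
#'   dimensions 1-6 observed in the training hairpins), or a
#'   [build_raw_features()] result (or list of them).
#' @return an object of class `quantile_codec`.
#' @export
fit_quantile_codec <- function(training_values) {
  if (inherits(training_values, "raw_features"))
    training_values <- list(training_values)
  if (is.list(training_values) &&
      all(vapply(training_values, inherits, logical(1), "raw_features")))
    training_values <- lapply(1:6, function(d)
      unlist(lapply(training_values, function(rf) rf[[paste0("d", d)]])))
  stopifnot(is.list(training_values), length(training_values) == 6L)
  bnds <- matrix(NA_real_, 4L, 6L,
                 dimnames = list(paste0("p", c(20, 40, 60, 80)),
                                 paste0("d", 1:6)))
  for (d in 1:6) {
    v <- training_values[[d]]
    v <- v[is.finite(v)]
    if (length(v) < 5L)
      stop("need at least 5 finite training values for dimension ", d)
    s <- sort(v)
    bnds[, d] <- s[ceiling(c(0.2, 0.4, 0.6, 0.8) * length(s))]
    if (length(unique(s)) == 1L)
      warning("all training values identical for dimension ", d,
              "; codec is degenerate")
  }
  structure(list(boundaries = bnds), class = "quantile_codec")
}

#' @export
print.quantile_codec <- function(x, ...) {
  cat("quantile_codec (20/40/60/80th percentile boundaries):\n")
  print(x$boundaries)
  invisible(x)
}

.encode_dim <- function(v, bnds) {
  # boundary values belong to the lower symbol: count boundaries < v
  idx <- rowSums(outer(v, bnds, ">")) + 1L
  idx[is.infinite(v) & v < 0] <- 6L # -Inf -> "F" (dimension 6 only)
  as.integer(idx)
}

#' Encode raw features into symbols
#'
#' Dimensions 1-6 map through the codec's percentile boundaries to
#' symbols A-E (plus F for `-Inf` in dimension 6); dimension 7 maps
#' nucleotides A/U/G/C to symbols A/B/C/D. `N` encodes as "A" with a
#' warning (positions are flagged in the raw features for downstream
#' filtering).
#'
#' @param raw a [build_raw_features()] result.
#' @param codec a [fit_quantile_codec()] result.
#' @return a `symbol_sequence`: integer matrix T x 7 of symbol indices.
#' @export
encode_features <- function(raw, codec) {
  stopifnot(inherits(raw, "raw_features"),
            inherits(codec, "quantile_codec"))
  T_ <- nrow(raw)
  m <- matrix(0L, T_, 7L)
  for (d in 1:6) m[, d] <- .encode_dim(raw[[paste0("d", d)]],
                                       codec$boundaries[, d])
  if (any(m[, 1:5] > 5L))
    stop("internal error: -Inf outside dimension 6")
  nt <- raw$d7
  if (any(nt == "N")) {
    warning(sum(nt == "N"), " N nucleotide(s) encoded as symbol A")
    nt[nt == "N"] <- "A"
  }
  m[, 7] <- match(nt, c("A", "U", "G", "C"))
  if (anyNA(m[, 7])) stop("invalid nucleotide in d7")
  structure(m, class = "symbol_sequence")
}

#' Symbol letters of an encoded sequence
#' @param symbols a `symbol_sequence`.
#' @return character matrix of symbols A-F.
#' @export
symbol_letters <- function(symbols) {
  m <- unclass(symbols)
  matrix(LETTERS[m], nrow(m), ncol(m))
}

#' Conservation tracks from a pairwise alignment
#'
#' Substitute conservation scores for genomes without precomputed
#' PhastCons/PhyloP: the PhyloP-like track scores 1 at alignment columns
#' with a matched nucleotide and 0 elsewhere; the PhastCons-like track
#' carries the supplied per-column alignment probability. Unaligned
#' positions score 0 in both tracks.
#'
#' @param maf path to a pairwise MAF file, or the result of
#'   [read_maf_pairwise()].
#' @param alignment_probabilities list with one numeric vector per
#'   alignment block (per-column alignment probabilities in `[0,1]`), or
#'   a single number recycled across all columns.
#' @param length target-sequence length.
#' @return a [conservation_tracks()].
#' @export
tracks_from_pairwise_alignment <- function(maf, alignment_probabilities,
                                           length) {
  blocks <- if (is.character(maf)) read_maf_pairwise(maf) else maf
  n <- as.integer(length)
  phylop <- numeric(n)
  phastcons <- numeric(n)
  if (is.numeric(alignment_probabilities) &&
      !is.list(alignment_probabilities))
    alignment_probabilities <- rep(list(alignment_probabilities),
                                   length(blocks))
  if (length(alignment_probabilities) != length(blocks))
    stop("need one probability vector per alignment block")
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    tgt <- strsplit(blk$text[1], "")[[1]]
    oth <- strsplit(blk$text[2], "")[[1]]
    if (length(tgt) != length(oth))
      stop("malformed MAF block ", b, ": unequal row widths")
    pr <- alignment_probabilities[[b]]
    if (length(pr) == 1L) pr <- rep(pr, length(tgt))
    if (length(pr) != length(tgt))
      stop("block ", b, ": ", length(pr), " probabilities for ",
           length(tgt), " columns")
    pos <- blk$start[1] # 0-based target coordinate
    for (col in seq_along(tgt)) {
      if (tgt[col] == "-") next
      pos <- pos + 1L # now 1-based position of this column
      if (pos > n) stop("block ", b, " extends past target length")
      if (oth[col] != "-") {
        phylop[pos] <- as.numeric(toupper(tgt[col]) == toupper(oth[col]))
        phastcons[pos] <- pr[col]
      }
    }
  }
  conservation_tracks(phastcons, phylop)
}
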