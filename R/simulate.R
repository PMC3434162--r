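#' Synthetic hairpin specification
#'
#' Parameters of the synthetic-genome generator. Defaults emulate the
#' anatomy and conservation profile of conserved miRNA hairpins: a ~22-nt
#' mature/passenger duplex on a stem with a 2-nt 3'-overhang geometry, a
#' lower stem of ~13 bp ending at the Drosha recognition base pair
#' (DRB), a terminal loop of 8-20 nt, conservation high (~0.9) over the
#' hairpin and low (~0.2) in the flanks with a sharp localized dip at
#' the DRB ~13 nt upstream of the duplex, a PhyloP-like track elevated
#' over the mature arm relative to the passenger arm, and a mature 5'
#' nucleotide that is predominantly U.
#'
#' @param mature_lengths,mature_length_probs mature-length distribution
#'   (default point mass at 22 nt).
#' @param arm_probs probabilities of the 3 mature locations
#'   (5'-arm, 3'-arm, both); must sum to 1.
#' @param loop_range inclusive range of terminal-loop lengths (nt).
#' @param lower_stem lower-stem length below the duplex (bp).
#' @param mutation_rate per-base substitution rate on the 3' stem side.
#' @param cons_duplex,cons_flank mean PhastCons-like level over the
#'   hairpin and in the flanks.
#' @param dip_depth depth of the DRB conservation/pairing dip.
#' @param noise_sd,phylop_noise_sd Gaussian noise on the tracks.
#' @param mature_boost PhyloP-like elevation of the mature arm.
#' @param p_u probability that the mature 5' nucleotide is U.
#' @return an object of class `hairpin_spec`.
#' @export
hairpin_spec <- function(mature_lengths = 22L, mature_length_probs = 1,
                         arm_probs = c(arm5 = 0.45, arm3 = 0.45,
                                       both = 0.10),
                         loop_range = c(8L, 20L), lower_stem = 13L,
                         mutation_rate = 0.03, cons_duplex = 0.9,
                         cons_flank = 0.2, dip_depth = 0.5,
                         noise_sd = 0.05, phylop_noise_sd = 0.1,
                         mature_boost = 0.25, p_u = 0.8) {
  stopifnot(length(mature_lengths) == length(mature_length_probs),
            all(mature_lengths >= 18L), all(mature_lengths <= 25L),
            abs(sum(arm_probs) - 1) < 1e-9, all(arm_probs >= 0),
            loop_range[1] >= 8L, loop_range[2] >= loop_range[1],
            lower_stem >= 1L, p_u >= 0, p_u <= 1)
  structure(as.list(environment()), class = "hairpin_spec")
}

.rand_nt <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)
.comp <- c(A = "T", C = "G", G = "C", T = "A")

#' Generate one synthetic hairpin
#'
#' Builds a hairpin region: 20-nt flank pad, lower stem, duplex (mature
#' and passenger strands offset by the 2-nt 3'-overhang convention),
#' terminal loop, and the mirrored 3' side. Emits the true pair map,
#' labels (M/P/L/F/N), and local conservation tracks with the DRB dips.
#'
#' @param spec a [hairpin_spec()].
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @return list with `sequence` (DNA string), `pair_map` (integer
#'   partner vector, NA = unpaired), `labels`, `tracks`
#'   ([conservation_tracks()]), and `truth` (duplex interval, mature
#'   interval(s), 5'-end position(s), arm type; local 1-based
#'   coordinates).
#' @export
generate_hairpin <- function(spec = hairpin_spec(), seed = 1L) {
  stopifnot(inherits(spec, "hairpin_spec"))
  set.seed(seed)
  m <- if (length(spec$mature_lengths) == 1L) spec$mature_lengths else
    sample(spec$mature_lengths, 1L, prob = spec$mature_length_probs)
  l <- sample(seq.int(spec$loop_range[1], spec$loop_range[2]), 1L)
  if (l < spec$loop_range[1]) stop("loop shorter than minimum")
  arm <- sample(c("arm5", "arm3", "both"), 1L, prob = spec$arm_probs)
  P0 <- 20L                      # flank pad
  S <- spec$lower_stem + 2L + m  # stem length per side
  H <- 2L * S + l                # hairpin core length
  n <- H + 2L * P0

  # build the 5' side + loop, mirror to the 3' side; stems are GC-biased
  # so the duplex binds stably under the pair-additive energy model
  side5 <- sample(c("A", "C", "G", "T"), S, replace = TRUE,
                  prob = c(0.15, 0.35, 0.35, 0.15))
  loop <- .rand_nt(l)
  side3 <- rev(unname(.comp[side5]))
  mut <- runif(S) < spec$mutation_rate
  side3[mut] <- .rand_nt(sum(mut))
  seq_all <- c(.rand_nt(P0), side5, loop, side3, .rand_nt(P0))

  # pair map over the stem (local coordinates include the flank pad)
  pair_map <- rep(NA_integer_, n)
  stem5 <- P0 + seq_len(S)
  partners <- P0 + H + 1L - seq_len(S)
  keep <- !mut
  pair_map[stem5[keep]] <- partners[keep]
  pair_map[partners[keep]] <- stem5[keep]

  strand5 <- c(P0 + S - m + 1L, P0 + S)            # duplex 5'-arm strand
  strand3 <- c(P0 + S + l + 3L, P0 + S + l + m + 2L) # 3'-arm strand
  duplex <- c(strand5[1], strand3[2])

  mature_iv <- switch(arm,
    arm5 = list(strand5), arm3 = list(strand3),
    both = list(strand5, strand3))
  five_ends <- vapply(mature_iv, `[`, integer(1), 1L)
  for (fe in five_ends)
    seq_all[fe] <- if (runif(1) < spec$p_u) "T" else
      sample(c("A", "C", "G"), 1L)

  labels <- rep("N", n)
  labels[duplex[1]:duplex[2]] <- "L"
  labels[strand5[1]:strand5[2]] <- if (arm == "arm3") "P" else "M"
  labels[strand3[1]:strand3[2]] <- if (arm == "arm5") "P" else "M"
  labels[(duplex[1] - 20L):(duplex[1] - 1L)] <- "F"
  labels[(duplex[2] + 1L):(duplex[2] + 20L)] <- "F"

  # conservation: high over the hairpin core, decaying into the flanks,
  # with localized dips at the DRB (~13 nt upstream of the duplex 5'
  # start and ~11 nt downstream of the duplex 3' end)
  pos <- seq_len(n)
  core <- as.numeric(pos > P0 & pos <= P0 + H)
  edge <- pmin(pmax((pos - P0) / 6, 0), 1) *
    pmin(pmax((P0 + H + 1 - pos) / 6, 0), 1)
  base <- spec$cons_flank + (spec$cons_duplex - spec$cons_flank) *
    core * edge
  dip <- function(center)
    spec$dip_depth * exp(-0.5 * ((pos - center) / 1.5)^2)
  base <- base - dip(duplex[1] - 13L) - dip(duplex[2] + 11L)
  phast <- pmin(pmax(base + rnorm(n, 0, spec$noise_sd), 0), 1)
  boost <- numeric(n)
  for (iv in mature_iv) boost[iv[1]:iv[2]] <- spec$mature_boost
  phylop <- pmax(base + boost + rnorm(n, 0, spec$phylop_noise_sd), 0)

  list(sequence = paste(seq_all, collapse = ""), pair_map = pair_map,
       labels = labels, tracks = conservation_tracks(phast, phylop),
       truth = list(duplex = duplex, mature = mature_iv,
                    five_ends = five_ends, arm = arm,
                    loop = c(strand5[2] + 1L, strand3[1] - 1L)))
}

#' Deduce the passenger strand from the mature interval
#'
#' Applies the 2-bp 3'-overhang rule: for a mature strand `[a, b]` with
#' pairing partner function `pi`, the passenger strand is
#' `[pi(b) + 2, pi(a) + 2]` (the same rule, via the orientation reversal
#' of `pi`, covers mature strands on either arm). Interval ends that are
#' unpaired are first repaired to the nearest paired position.
#'
#' @param mature integer vector `c(start, end)` (1-based inclusive).
#' @param pair_map integer partner vector (NA = unpaired).
#' @return integer vector `c(start, end)` of the passenger strand.
#' @export
deduce_passenger <- function(mature, pair_map) {
  stopifnot(length(mature) == 2L, mature[1] <= mature[2])
  repair <- function(pos) {
    if (!is.na(pair_map[pos])) return(pos)
    paired <- which(!is.na(pair_map))
    paired <- paired[paired >= mature[1] & paired <= mature[2]]
    if (!length(paired))
      stop("no paired position within the mature interval")
    paired[which.min(abs(paired - pos))]
  }
  a <- repair(mature[1]); b <- repair(mature[2])
  unname(sort(c(pair_map[a], pair_map[b])) + 2L)
}

#' Standardize a hairpin into a labeled 200-nt window
#'
#' Centers the duplex in a fixed-length window, extends the flanks with
#' background sequence and low conservation, and returns the labeled
#' example with window-local truth coordinates.
#'
#' @param hp a [generate_hairpin()] result.
#' @param window window length (nt).
#' @param spec the [hairpin_spec()] used (for background track levels).
#' @param seed RNG seed for the padded flanks.
#' @return list with `sequence`, `tracks`, `labels`, `truth` (window
#'   coordinates).
#' @export
standardize_window <- function(hp, window = 200L, spec = hairpin_spec(),
                               seed = 1L) {
  n <- nchar(hp$sequence)
  if (n > window)
    stop(sprintf("hairpin region (%d nt) longer than window (%d nt)",
                 n, window))
  set.seed(seed)
  d_center <- floor(mean(hp$truth$duplex))
  left <- floor(window / 2) - d_center
  left <- max(0L, min(window - n, left))
  right <- window - n - left
  pad_tracks <- function(k) {
    ph <- pmin(pmax(rnorm(k, spec$cons_flank, spec$noise_sd), 0), 1)
    pp <- pmax(rnorm(k, spec$cons_flank, spec$phylop_noise_sd), 0)
    list(ph = ph, pp = pp)
  }
  lp <- pad_tracks(left); rp <- pad_tracks(right)
  sequence <- paste0(paste(.rand_nt(left), collapse = ""), hp$sequence,
                     paste(.rand_nt(right), collapse = ""))
  tracks <- conservation_tracks(
    c(lp$ph, hp$tracks$phastcons, rp$ph),
    c(lp$pp, hp$tracks$phylop, rp$pp))
  labels <- c(rep("N", left), hp$labels, rep("N", right))
  shift_iv <- function(iv) iv + left
  truth <- list(duplex = shift_iv(hp$truth$duplex),
                mature = lapply(hp$truth$mature, shift_iv),
                five_ends = hp$truth$five_ends + left,
                arm = hp$truth$arm, loop = shift_iv(hp$truth$loop))
  list(sequence = sequence, tracks = tracks, labels = labels,
       truth = truth)
}

#' Generate a synthetic genome with planted hairpins and decoys
#'
#' A background sequence with non-conserved flank-level conservation,
#' `n_hairpins` planted hairpin windows, and `n_decoys` conserved
#' non-hairpin blocks (mean conservation > 0.6, random sequence) that
#' make the negatives hard. Hairpins and decoys are spaced at least
#' 200 nt apart.
#'
#' @param n_hairpins number of hairpins to plant.
#' @param background_length total genome length (nt).
#' @param spec a [hairpin_spec()].
#' @param seed RNG seed.
#' @param n_decoys number of conserved decoy blocks.
#' @param decoy_length decoy block length (nt).
#' @return an object of class `synthetic_bundle`: list with `sequence`,
#'   `tracks`, `truth` (data frame of hairpin records plus window truth
#'   list), `decoys` (data frame of intervals), and `seed`.
#' @export
generate_genome <- function(n_hairpins, background_length,
                            spec = hairpin_spec(), seed = 1L,
                            n_decoys = n_hairpins,
                            decoy_length = 200L) {
  set.seed(seed)
  n <- as.integer(background_length)
  win <- 200L
  n_blocks <- n_hairpins + n_decoys
  need <- n_blocks * (win + 200L) + 200L
  if (n < need)
    stop(sprintf("background of %d nt cannot host %d blocks with 200-nt spacing (need >= %d)",
                 n, n_blocks, need))
  sequence <- .rand_nt(n)
  phast <- pmin(pmax(rnorm(n, spec$cons_flank, spec$noise_sd), 0), 1)
  phylop <- pmax(rnorm(n, spec$cons_flank, spec$phylop_noise_sd), 0)

  # evenly spaced slots with jitter, shuffled between hairpins/decoys
  slot_pitch <- as.integer((n - 200L) %/% n_blocks)
  starts <- 100L + (seq_len(n_blocks) - 1L) * slot_pitch +
    sample.int(max(1L, slot_pitch - win - 200L), n_blocks,
               replace = TRUE)
  starts <- pmax(1L, (starts %/% 50L) * 50L) # align to a coarse grid
  kind <- sample(rep(c("hairpin", "decoy"),
                     c(n_hairpins, n_decoys)))
  hp_rows <- list(); windows <- list(); decoys <- list()
  hp_seed <- sample.int(.Machine$integer.max %/% 2L, n_blocks)
  for (b in seq_len(n_blocks)) {
    s <- starts[b]
    if (kind[b] == "hairpin") {
      hp <- generate_hairpin(spec, seed = hp_seed[b])
      w <- standardize_window(hp, win, spec, seed = hp_seed[b] + 1L)
      idx <- s:(s + win - 1L)
      sequence[idx] <- strsplit(w$sequence, "")[[1]]
      phast[idx] <- w$tracks$phastcons
      phylop[idx] <- w$tracks$phylop
      i <- length(hp_rows) + 1L
      hp_rows[[i]] <- data.frame(
        window_start = s, window_end = s + win - 1L,
        hairpin_start = s + w$truth$duplex[1] - 21L,
        hairpin_end = s + w$truth$duplex[2] + 19L,
        duplex_start = s + w$truth$duplex[1] - 1L,
        duplex_end = s + w$truth$duplex[2] - 1L,
        arm = w$truth$arm,
        five_end_1 = s + w$truth$five_ends[1] - 1L,
        five_end_2 = if (length(w$truth$five_ends) > 1L)
          s + w$truth$five_ends[2] - 1L else NA_integer_)
      w$genome_offset <- s - 1L
      windows[[i]] <- w
    } else {
      idx <- s:(s + decoy_length - 1L)
      lvl <- runif(1, 0.65, 0.85)
      phast[idx] <- pmin(pmax(rnorm(decoy_length, lvl, spec$noise_sd),
                              0), 1)
      phylop[idx] <- pmax(rnorm(decoy_length, lvl,
                                spec$phylop_noise_sd), 0)
      decoys[[length(decoys) + 1L]] <-
        data.frame(start = s, end = s + decoy_length - 1L)
    }
  }
  truth_df <- if (length(hp_rows)) do.call(rbind, hp_rows) else
    data.frame()
  decoy_df <- if (length(decoys)) do.call(rbind, decoys) else
    data.frame()
  structure(list(sequence = paste(sequence, collapse = ""),
                 tracks = conservation_tracks(phast, phylop),
                 truth = truth_df, windows = windows,
                 decoys = decoy_df, seed = seed, spec = spec),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(
    "synthetic_bundle: %d nt, %d hairpin(s), %d decoy block(s), seed %d\n",
    nchar(x$sequence), nrow(x$truth), nrow(x$decoys), x$seed))
  invisible(x)
}

#' Sample fixed-length background (non-miRNA) regions
#'
#' Draws `n_low` windows with mean PhastCons-like score < 0.4 and
#' `n_high` with mean > 0.6, each of length `window`, avoiding `exclude`
#' intervals (e.g. truth hairpins) and each other.
#'
#' @param tracks a [conservation_tracks()].
#' @param n_low,n_high number of windows per conservation band.
#' @param window window length (nt).
#' @param seed RNG seed.
#' @param exclude data.frame with `start`/`end` columns to avoid.
#' @return data.frame with `start`, `end`, `mean_phastcons`, `band`.
#' @export
sample_background_regions <- function(tracks, n_low, n_high,
                                      window = 200L, seed = 1L,
                                      exclude = NULL) {
  set.seed(seed)
  n <- tracks$length
  cand <- seq.int(1L, n - window + 1L, by = max(1L, window %/% 4L))
  cs <- c(0, cumsum(tracks$phastcons))
  means <- (cs[cand + window] - cs[cand]) / window
  blocked <- rep(FALSE, n)
  if (!is.null(exclude) && nrow(exclude))
    for (r in seq_len(nrow(exclude)))
      blocked[exclude$start[r]:exclude$end[r]] <- TRUE
  free <- vapply(cand, function(s) !any(blocked[s:(s + window - 1L)]),
                 logical(1))
  pick <- function(idx, k, band) {
    idx <- sample(idx)
    chosen <- integer()
    for (s in idx) {
      if (length(chosen) == k) break
      if (any(blocked[s:(s + window - 1L)])) next
      blocked[s:(s + window - 1L)] <<- TRUE
      chosen <- c(chosen, s)
    }
    if (length(chosen) < k)
      warning(sprintf("only %d of %d %s-conservation windows found",
                      length(chosen), k, band))
    chosen
  }
  low <- pick(cand[free & means < 0.4], n_low, "low")
  high <- pick(cand[free & means > 0.6], n_high, "high")
  starts <- c(low, high)
  data.frame(start = starts, end = starts + window - 1L,
             mean_phastcons = (cs[starts + window] - cs[starts]) / window,
             band = rep(c("low", "high"), c(length(low), length(high))))
}
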