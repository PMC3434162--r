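#' Build labeled training examples from a synthetic bundle
#'
#' Positive examples are the standardized hairpin windows; negative
#' examples are 200-nt background regions sampled from the low- and
#' high-conservation bands, labeled all-N. Each window is folded and
#' featurized independently; the quantile codec is fitted on the raw
#' feature values of the positive (hairpin) windows only.
#'
#' @param bundle a [generate_genome()] bundle.
#' @param n_low,n_high negative windows per conservation band.
#' @param fold_cfg a [fold_config()].
#' @param pair_threshold BPP threshold for the base-pair distance.
#' @param seed seed for background sampling.
#' @param keep_hairpins logical vector selecting which of the bundle's
#'   hairpins to use (family/homolog exclusion).
#' @param codec optionally reuse an existing codec instead of fitting.
#' @return list with `examples` (list of [labeled_example()]),
#'   `codec`, and `raws` (raw features of the positive windows).
#' @export
bundle_examples <- function(bundle, n_low = NULL, n_high = NULL,
                            fold_cfg = fold_config(),
                            pair_threshold = 0.5, seed = 1L,
                            keep_hairpins = NULL, codec = NULL) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  wins <- bundle$windows
  if (!is.null(keep_hairpins)) wins <- wins[keep_hairpins]
  raws <- lapply(wins, function(w) {
    bpm <- compute_pair_probabilities(w$sequence, fold_cfg)
    build_raw_features(w$sequence, w$tracks, bpm, pair_threshold)
  })
  if (is.null(codec)) codec <- fit_quantile_codec(raws)
  pos <- lapply(seq_along(wins), function(i)
    labeled_example(encode_features(raws[[i]], codec),
                    wins[[i]]$labels, id = paste0("hairpin_", i)))
  n_hp <- length(bundle$windows)
  if (is.null(n_low)) n_low <- ceiling(n_hp / 2)
  if (is.null(n_high)) n_high <- floor(n_hp / 2)
  excl <- data.frame(start = bundle$truth$window_start,
                     end = bundle$truth$window_end)
  bg <- sample_background_regions(bundle$tracks, n_low, n_high,
                                  window = 200L, seed = seed,
                                  exclude = excl)
  neg <- lapply(seq_len(nrow(bg)), function(i) {
    s <- bg$start[i]; e <- bg$end[i]
    sub <- substr(bundle$sequence, s, e)
    tr <- conservation_tracks(bundle$tracks$phastcons[s:e],
                              bundle$tracks$phylop[s:e])
    bpm <- compute_pair_probabilities(sub, fold_cfg)
    raw <- build_raw_features(sub, tr, bpm, pair_threshold)
    labeled_example(encode_features(raw, codec),
                    rep("N", e - s + 1L),
                    id = paste0("bg_", bg$band[i], "_", i))
  })
  list(examples = c(pos, neg), codec = codec, raws = raws)
}

#' Train a scanning model from synthetic bundles
#'
#' Featurizes the bundles' hairpin windows and sampled background
#' regions, fits the quantile codec on the hairpin windows, and selects
#' the Gaussian-prior constant by held-out F-score. Returns a
#' self-contained `crf_model`.
#'
#' @param bundles list of [generate_genome()] bundles.
#' @param config a [training_config()].
#' @param keep_hairpins optional list (parallel to `bundles`) of
#'   logical vectors for family/homolog exclusion.
#' @param arch an [arch_config()].
#' @param fold_cfg a [fold_config()].
#' @param pair_threshold BPP threshold for the base-pair distance.
#' @return a `crf_model` with `graph`, `params`, `codec` and `meta`
#'   (selected penalty, selection report).
#' @export
train_on_bundles <- function(bundles, config = training_config(),
                             keep_hairpins = NULL,
                             arch = arch_config(),
                             fold_cfg = fold_config(),
                             pair_threshold = 0.5) {
  if (inherits(bundles, "synthetic_bundle")) bundles <- list(bundles)
  graph <- build_state_graph(arch)
  # fit one codec on the hairpin windows of every training bundle
  all_raws <- list()
  for (b in seq_along(bundles)) {
    wins <- bundles[[b]]$windows
    if (!is.null(keep_hairpins)) wins <- wins[keep_hairpins[[b]]]
    all_raws <- c(all_raws, lapply(wins, function(w) {
      bpm <- compute_pair_probabilities(w$sequence, fold_cfg)
      build_raw_features(w$sequence, w$tracks, bpm, pair_threshold)
    }))
  }
  codec <- fit_quantile_codec(all_raws)
  all_ex <- list()
  for (b in seq_along(bundles)) {
    be <- bundle_examples(bundles[[b]], fold_cfg = fold_cfg,
                          pair_threshold = pair_threshold,
                          seed = config$rng_seed + b,
                          keep_hairpins = keep_hairpins[[b]],
                          codec = codec)
    all_ex <- c(all_ex, be$examples)
  }
  sel <- select_penalty(all_ex, graph, config)
  structure(list(graph = graph, params = sel$params_best,
                 codec = codec,
                 meta = list(c_best = sel$c_best,
                             report = sel$report,
                             pair_threshold = pair_threshold,
                             fold = unclass(fold_cfg)[
                               c("max_span", "min_loop",
                                 "temperature_scale")])),
            class = "crf_model")
}
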