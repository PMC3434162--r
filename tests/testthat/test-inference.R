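test_that("hairpin probability is the complement of the non-miRNA posterior", {
  g <- toy_graph()
  sym <- random_symbols(8, seed = 71)
  set.seed(72)
  p <- crf_params(g, rnorm(crf_params(g)$J, 0, 0.5))
  post <- forward_backward(p, g, sym)
  pmi <- hairpin_probability(post, g)
  expect_lt(max(abs(pmi - (1 - post[, 3]))), 1e-12)
  p5 <- mature_5end_probability(post, g)
  expect_true(all(p5 <= pmi + 1e-12))
  expect_true(all(pmi >= 0 & pmi <= 1 + 1e-12))
})

test_that("degenerate posterior masses give 0/1 probabilities", {
  g <- toy_graph()
  post <- matrix(0, 3, 3)
  post[, 3] <- 1 # all mass on Non-miRNA
  expect_equal(hairpin_probability(post, g), c(0, 0, 0))
  post2 <- matrix(0, 2, 3); post2[, 2] <- 1 # all mass on Loop
  expect_equal(hairpin_probability(post2, g), c(1, 1))
  expect_equal(mature_5end_probability(post2, g), c(0, 0))
  post3 <- matrix(0, 2, 3); post3[, 1] <- 1 # all mass on Mature entry
  expect_equal(mature_5end_probability(post3, g), c(1, 1))
})

test_that("segment calling enforces the 80/150 length rules", {
  mk <- function(len) c(rep(0, 10), rep(0.9, len), rep(0, 10))
  expect_equal(nrow(call_hairpins(mk(79), 0.5)), 0L)
  expect_equal(nrow(call_hairpins(mk(80), 0.5)), 1L)
  expect_equal(nrow(call_hairpins(mk(149), 0.5)), 1L)
  expect_equal(nrow(call_hairpins(mk(150), 0.5)), 0L)
  s <- call_hairpins(mk(100), 0.5)
  expect_equal(c(s$start, s$end), c(11, 110))
  expect_equal(s$score, 0.9)
  # strict inequality: values equal to T do not qualify
  expect_equal(nrow(call_hairpins(rep(0.5, 100), 0.5)), 0L)
})

test_that("5'-end calling is thresholded and gated", {
  p5 <- c(rep(0, 5), 0.3, 0.6, 0.2, rep(0, 92), 0.7, 0)
  calls <- call_5ends(p5, 0.4, gate = FALSE)
  expect_equal(calls$pos, c(7, 101))
  segs <- data.frame(start = 1, end = 50, score = 1)
  gated <- call_5ends(p5, 0.4, segs, gate = TRUE)
  expect_equal(gated$pos, 7)
  expect_true(all(gated$pos %in% calls$pos))
  expect_equal(nrow(call_5ends(p5, 1 - 1e-12, gate = FALSE)), 0L)
})

test_that("raising the threshold never lengthens segments nor adds calls", {
  set.seed(73)
  pmi <- pmin(1, pmax(0, cumsum(rnorm(600, 0, 0.1)) * 0.1 + 0.5))
  p5 <- pmi * runif(600)
  lo <- call_hairpins(pmi, 0.3); hi <- call_hairpins(pmi, 0.6)
  tot <- function(s) if (nrow(s)) sum(s$end - s$start + 1) else 0
  expect_lte(tot(hi), tot(lo))
  c_lo <- call_5ends(p5, 0.3, gate = FALSE)$pos
  c_hi <- call_5ends(p5, 0.6, gate = FALSE)$pos
  expect_true(all(c_hi %in% c_lo))
})

test_that("windowed scanning matches the unwindowed computation", {
  set.seed(74)
  bundle <- generate_genome(2, 6000, seed = 75)
  model <- suppressWarnings(
    train_on_bundles(bundle,
                     config = training_config(penalty_grid = 10,
                                              rng_seed = 76,
                                              max_iter = 60)))
  # short sequence: one window equals the direct computation
  s <- substr(bundle$sequence, 1, 800)
  tr <- conservation_tracks(bundle$tracks$phastcons[1:800],
                            bundle$tracks$phylop[1:800])
  pred1 <- scan_genome(model, s, tr, window = 900, overlap = 300)
  bpm <- compute_pair_probabilities(s, fold_config())
  raw <- build_raw_features(s, tr, bpm, 0.5)
  post <- forward_backward(model$params, model$graph,
                           encode_features(raw, model$codec))
  expect_lt(max(abs(pred1$p_mi - hairpin_probability(post, model$graph))),
            1e-12)
  # stitched interior positions match the full-sequence posteriors
  # (sequence built so window boundaries fall over background, away
  # from the planted hairpin)
  set.seed(78)
  hp <- standardize_window(generate_hairpin(seed = 78), seed = 79)
  pad <- function(k) list(
    nt = paste(sample(c("A", "C", "G", "T"), k, TRUE), collapse = ""),
    ph = pmin(pmax(rnorm(k, 0.2, 0.05), 0), 1),
    pp = pmax(rnorm(k, 0.2, 0.1), 0))
  lp <- pad(700); rp <- pad(700)
  s2 <- paste0(lp$nt, hp$sequence, rp$nt)
  tr2 <- conservation_tracks(c(lp$ph, hp$tracks$phastcons, rp$ph),
                             c(lp$pp, hp$tracks$phylop, rp$pp))
  full <- scan_genome(model, s2, tr2, window = 2200, overlap = 300)
  stitched <- scan_genome(model, s2, tr2, window = 1400, overlap = 400)
  # positions more than `overlap` from every boundary of their source
  # window; the hairpin (701-900) lies well inside
  interior <- 401:1000
  expect_lt(max(abs(full$p_mi[interior] - stitched$p_mi[interior])), 1e-6)
})

test_that("scan window/overlap preconditions are enforced", {
  bundle <- generate_genome(2, 6000, seed = 77)
  fake_model <- structure(
    list(graph = build_state_graph(),
         params = crf_params(build_state_graph()),
         codec = fit_quantile_codec(lapply(1:6, function(d) 1:10))),
    class = "crf_model")
  expect_error(scan_genome(fake_model, "ACGT", conservation_tracks(
    rep(0, 4), rep(0, 4)), window = 200, overlap = 300), ">= 300")
  expect_error(scan_genome(fake_model, strrep("A", 1000),
                           conservation_tracks(rep(0, 1000),
                                               rep(0, 1000)),
                           window = 300, overlap = 400), "exceed")
})

test_that("a planted hairpin is recovered as an overlapping segment", {
  bundle <- generate_genome(5, 15000, seed = 7)
  model <- suppressWarnings(
    train_on_bundles(bundle,
                     config = training_config(penalty_grid = 10,
                                              rng_seed = 7,
                                              max_iter = 80)))
  pred <- scan_genome(model, bundle$sequence, bundle$tracks,
                      window = 2000, overlap = 400, t_hairpin = 0.5)
  tr <- bundle$truth
  overlaps <- vapply(seq_len(nrow(tr)), function(h) {
    if (!nrow(pred$segments)) return(0)
    max(0, pmin(pred$segments$end, tr$hairpin_end[h]) -
          pmax(pred$segments$start, tr$hairpin_start[h]) + 1)
  }, numeric(1))
  expect_gte(max(overlaps), 60L)
})
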