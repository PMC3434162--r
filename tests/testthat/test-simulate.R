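test_that("hairpin generation is deterministic under the seed", {
  a <- generate_hairpin(seed = 81)
  b <- generate_hairpin(seed = 81)
  expect_identical(a, b)
  c <- generate_hairpin(seed = 82)
  expect_false(identical(a$sequence, c$sequence))
})

test_that("mature 5' nucleotide is U at the configured rate", {
  spec <- hairpin_spec(p_u = 0.8)
  hits <- vapply(1:1000, function(s) {
    hp <- generate_hairpin(spec, seed = 8000 + s)
    fe <- hp$truth$five_ends[1]
    substr(hp$sequence, fe, fe) == "T"
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.8), 0.04)
})

test_that("generated duplexes fold back with high pair probability", {
  ok_frac <- vapply(1:20, function(s) {
    hp <- generate_hairpin(seed = 8200 + s)
    prof <- pairing_profile(compute_pair_probabilities(hp$sequence))
    duplex_strands <- unlist(lapply(list(
      hp$truth$mature[[1]],
      deduce_passenger(hp$truth$mature[[1]], hp$pair_map)),
      function(iv) iv[1]:iv[2]))
    mean(prof$bpp[duplex_strands] >= 0.5)
  }, numeric(1))
  expect_gte(mean(ok_frac >= 0.7), 0.9)
  expect_gt(mean(ok_frac), 0.8)
  expect_gt(min(ok_frac), 0.6)
})

test_that("passenger deduction implements the 2-bp 3'-overhang rule", {
  # worked example: perfect stem pairing i <-> 99 - i (0-based),
  # mature [5, 26] -> partners 73/94 -> passenger [75, 96]
  pm <- rep(NA_integer_, 100)
  for (i in 0:99) pm[i + 1] <- (99 - i) + 1 # 1-based storage
  pass <- deduce_passenger(c(5, 26) + 1, pm) - 1 # back to 0-based
  expect_equal(pass, c(75, 96))
  # length preserved and involution returns the original interval
  expect_equal(diff(pass), 26 - 5)
  back <- deduce_passenger(pass + 1, pm) - 1
  expect_equal(back, c(5, 26))
  # unpaired ends are repaired to the nearest paired position
  pm2 <- pm; pm2[6] <- NA
  expect_equal(deduce_passenger(c(6, 27), pm2),
               deduce_passenger(c(7, 27), pm2))
  expect_error(deduce_passenger(c(3, 5), rep(NA_integer_, 10)),
               "no paired position")
})

test_that("deduced passenger matches the generator's annotation", {
  for (s in 83:86) {
    hp <- generate_hairpin(seed = s)
    if (hp$truth$arm != "arm5") next
    mat <- hp$truth$mature[[1]]
    pass <- deduce_passenger(mat, hp$pair_map)
    expect_equal(pass[2] - pass[1], mat[2] - mat[1])
    lab_run <- range(which(hp$labels == "P"))
    expect_equal(pass, lab_run)
  }
})

test_that("synthetic genomes respect spacing and conservation bands", {
  bundle <- generate_genome(6, 20000, seed = 87)
  tr <- bundle$truth
  expect_equal(nrow(tr), 6L)
  # truth windows never overlap
  ord <- order(tr$window_start)
  expect_true(all(tr$window_start[ord][-1] > tr$window_end[ord][-6]))
  # decoy blocks are conserved, background is not
  dec_means <- vapply(seq_len(nrow(bundle$decoys)), function(d)
    mean(bundle$tracks$phastcons[bundle$decoys$start[d]:
                                   bundle$decoys$end[d]]), numeric(1))
  expect_true(all(dec_means > 0.6))
  blocked <- rep(FALSE, 20000)
  for (r in seq_len(nrow(tr)))
    blocked[tr$window_start[r]:tr$window_end[r]] <- TRUE
  for (d in seq_len(nrow(bundle$decoys)))
    blocked[bundle$decoys$start[d]:bundle$decoys$end[d]] <- TRUE
  expect_lt(mean(bundle$tracks$phastcons[!blocked]), 0.4)
  # determinism
  expect_identical(bundle$sequence,
                   generate_genome(6, 20000, seed = 87)$sequence)
  # zero hairpins: pure background
  empty <- generate_genome(0, 12000, seed = 88, n_decoys = 2)
  expect_equal(nrow(empty$truth), 0L)
})

test_that("background region sampling respects bands, length and exclusions", {
  bundle <- generate_genome(4, 20000, seed = 89)
  excl <- data.frame(start = bundle$truth$window_start,
                     end = bundle$truth$window_end)
  bg <- sample_background_regions(bundle$tracks, 3, 3, seed = 90,
                                  exclude = excl)
  expect_true(all(bg$end - bg$start + 1L == 200L))
  expect_true(all(bg$mean_phastcons[bg$band == "low"] < 0.4))
  expect_true(all(bg$mean_phastcons[bg$band == "high"] > 0.6))
  for (r in seq_len(nrow(bg)))
    expect_false(any(bg$start[r] <= excl$end & bg$end[r] >= excl$start))
  expect_identical(bg, sample_background_regions(bundle$tracks, 3, 3,
                                                 seed = 90,
                                                 exclude = excl))
  # insufficient windows yield a partial result with a warning
  flat <- conservation_tracks(rep(0.5, 2000), rep(0, 2000))
  expect_warning(few <- sample_background_regions(flat, 2, 2, seed = 91),
                 "0 of 2")
  expect_equal(nrow(few), 0L)
})

test_that("standardized windows have the canonical label anatomy", {
  for (s in 92:94) {
    hp <- generate_hairpin(seed = s)
    w <- standardize_window(hp, seed = s + 100)
    expect_equal(nchar(w$sequence), 200L)
    expect_equal(length(w$labels), 200L)
    expect_length(validate_labels(w$labels), 0)
    r <- rle(w$labels)
    runs <- split(r$lengths, r$values)
    expect_equal(unname(runs$F), c(20, 20))
    expect_true(all(runs$M >= 18 & runs$M <= 25))
    expect_true(all(runs$L >= 8))
    if (hp$truth$arm != "both") expect_true(all(runs$P >= 18 & runs$P <= 25))
    # duplex centered
    ctr <- mean(w$truth$duplex)
    expect_lt(abs(ctr - 100.5), 2)
    # hairpin longer than the window is refused
    expect_error(standardize_window(hp, window = 100), "longer")
  }
})

test_that("synthetic profiles reproduce the expected conservation anatomy", {
  raws <- list(); anchors_d <- integer(); m_meds <- c(); p_meds <- c()
  drb <- c()
  for (s in 1:40) {
    hp <- generate_hairpin(seed = 9500 + s)
    drb_pos <- hp$truth$duplex[1] - 13L
    tr <- hp$tracks$phastcons
    drb <- rbind(drb, tr[drb_pos + c(-5, 0, 5)])
    if (hp$truth$arm == "arm5") {
      mat <- hp$truth$mature[[1]]
      pas <- deduce_passenger(mat, hp$pair_map)
      m_meds <- c(m_meds, median(hp$tracks$phylop[mat[1]:mat[2]]))
      p_meds <- c(p_meds, median(hp$tracks$phylop[pas[1]:pas[2]]))
    }
  }
  # DRB dip: mean at the dip below both +-5 positions
  mu <- colMeans(drb)
  expect_lt(mu[2], mu[1])
  expect_lt(mu[2], mu[3])
  # mature arm PhyloP-like exceeds passenger arm
  expect_gt(median(m_meds), median(p_meds))
})
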