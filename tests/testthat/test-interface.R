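test_that("FASTA I/O round-trips, preserves order, and rejects duplicates", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">seq2 desc", "ACGTAC", "GT", ">seq1", "ttgga"), fa)
  seqs <- read_fasta(fa)
  expect_equal(names(seqs), c("seq2", "seq1"))
  expect_equal(unname(seqs[1]), "ACGTACGT")
  expect_equal(unname(seqs[2]), "TTGGA") # case-folded
  # CRLF input
  fa2 <- tempfile(fileext = ".fa")
  writeBin(charToRaw(">a\r\nACGT\r\n"), fa2)
  expect_equal(unname(read_fasta(fa2)), "ACGT")
  # duplicates
  fa3 <- tempfile(fileext = ".fa")
  writeLines(c(">a", "AC", ">a", "GT"), fa3)
  expect_error(read_fasta(fa3), "duplicate")
  # write round-trip
  fa4 <- tempfile(fileext = ".fa")
  write_fasta(c(x = "ACGT", y = "GGCC"), fa4)
  expect_equal(read_fasta(fa4), c(x = "ACGT", y = "GGCC"))
})

test_that("bedGraph tracks read into dense arrays", {
  bg <- tempfile(fileext = ".bedGraph")
  writeLines(c("track type=bedGraph", "chr1\t0\t3\t0.5", "chr1\t5\t7\t0.9"),
             bg)
  v <- read_track(bg, 10)
  expect_equal(v, c(0.5, 0.5, 0.5, NA, NA, 0.9, 0.9, NA, NA, NA))
  # out-of-range interval errors with a line number
  bad <- tempfile(); writeLines("chr1\t8\t12\t1", bad)
  expect_error(read_track(bad, 10), "line 1")
  # overlapping intervals: last wins with a warning
  ov <- tempfile()
  writeLines(c("chr1\t0\t4\t1", "chr1\t2\t5\t2"), ov)
  expect_warning(v2 <- read_track(ov, 6), "last wins")
  expect_equal(v2, c(1, 1, 2, 2, 2, NA))
})

test_that("fixed-step wiggle is 1-based and converts correctly", {
  wig <- tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=1 step=1", "0.1", "0.2",
               "fixedStep chrom=chr1 start=8 step=2 span=2",
               "0.7", "0.8"), wig)
  v <- read_track(wig, 12)
  expect_equal(v[1:2], c(0.1, 0.2)) # start=1 maps to index 1
  expect_equal(v[8:11], c(0.7, 0.7, 0.8, 0.8))
  expect_true(all(is.na(v[c(3:7, 12)])))
})

test_that("bedGraph writer merges runs and round-trips", {
  x <- c(0.5, 0.5, 0.2, NA, 0.2)
  bg <- tempfile()
  write_bedgraph(x, bg)
  lines <- readLines(bg)
  expect_equal(length(lines), 3) # two merged runs + final value
  expect_equal(read_track(bg, 5), x)
})

test_that("predictions write as BED6 and round-trip through the reader", {
  pred <- structure(list(
    segments = data.frame(start = 101, end = 200, score = 0.93,
                          strand = "+"),
    five_prime = data.frame(pos = 120, p = 0.4, strand = "+"),
    p_mi = c(rep(0, 100), rep(0.93, 100)),
    p_5end = rep(0.01, 200), t_hairpin = 0.5, t_5end = 0.5),
    class = "prediction")
  sp <- tempfile(fileext = ".bed"); fp <- tempfile(fileext = ".bed")
  pm <- tempfile(fileext = ".bedGraph")
  write_predictions(pred, sp, fp, p_mi_path = pm)
  segs <- read_bed(sp)
  expect_equal(segs$start, 101) # 0-based on disk, 1-based in memory
  expect_equal(segs$end, 200)
  expect_equal(segs$score, 930)
  calls <- read_bed(fp)
  expect_equal(calls$start, 120)
  expect_equal(calls$end, 120)
  expect_equal(read_track(pm, 200), pred$p_mi)
  # empty predictions give empty (but readable) files
  empty <- structure(list(
    segments = data.frame(start = integer(), end = integer(),
                          score = numeric(), strand = character()),
    five_prime = data.frame(pos = integer(), p = numeric(),
                            strand = character()),
    p_mi = numeric(), p_5end = numeric(), t_hairpin = .5, t_5end = .5),
    class = "prediction")
  write_predictions(empty, sp, fp)
  expect_equal(nrow(read_bed(sp)), 0L)
})

test_that("model serialization round-trips graph, weights and codec", {
  g <- build_state_graph()
  set.seed(121)
  p <- crf_params(g, rnorm(crf_params(g)$J, 0, 0.1))
  codec <- fit_quantile_codec(lapply(1:6, function(d) rnorm(50)))
  model <- structure(list(graph = g, params = p, codec = codec,
                          meta = list(c_best = 10)),
                     class = "crf_model")
  path <- tempfile(fileext = ".json")
  write_model(model, path)
  m2 <- read_model(path)
  expect_equal(m2$params$m, p$m)
  expect_equal(m2$graph$edges, g$edges)
  expect_equal(m2$graph$s_5end, g$s_5end)
  expect_equal(unname(m2$codec$boundaries), unname(codec$boundaries))
  expect_equal(m2$meta$c_best, 10)
  expect_error(read_model(tempfile()), ".")
})

test_that("the CLI handles help, unknown flags and missing files", {
  expect_equal(crf_cli(character()), 0L)
  expect_output(crf_cli("--help"), "usage")
  expect_equal(suppressMessages(crf_cli("frobnicate")), 2L)
  expect_output(crf_cli(c("scan", "--help")), "usage")
  expect_equal(suppressMessages(
    crf_cli(c("scan", "--model", "/nonexistent.json",
              "--fasta", "x.fa", "--phastcons", "a", "--phylop", "b",
              "--segments", "s.bed", "--five-prime", "f.bed"))), 1L)
  expect_equal(suppressMessages(crf_cli(c("fold", "--bogus"))), 1L)
})

test_that("the CLI pipeline runs simulate -> train -> scan -> eval", {
  dir <- tempfile(); dir.create(dir)
  px <- file.path(dir, "sim")
  expect_equal(crf_cli(c("simulate", "--n-hairpins", "6", "--length",
                         "16000", "--seed", "5", "--out-prefix", px)),
               0L)
  expect_true(file.exists(paste0(px, ".fa")))
  model <- file.path(dir, "model.json")
  status <- suppressWarnings(suppressMessages(
    crf_cli(c("train", "--fasta", paste0(px, ".fa"),
              "--phastcons", paste0(px, ".phastcons.bedGraph"),
              "--phylop", paste0(px, ".phylop.bedGraph"),
              "--labels", paste0(px, ".truth.bed"),
              "--model", model,
              "--penalty-grid", "10", "--max-iter", "50",
              "--seed", "5"))))
  expect_equal(status, 0L)
  expect_true(file.exists(model))
  segs <- file.path(dir, "segs.bed"); fps <- file.path(dir, "5p.bed")
  expect_equal(suppressMessages(
    crf_cli(c("scan", "--model", model, "--fasta", paste0(px, ".fa"),
              "--phastcons", paste0(px, ".phastcons.bedGraph"),
              "--phylop", paste0(px, ".phylop.bedGraph"),
              "--segments", segs, "--five-prime", fps))), 0L)
  truth_bed <- file.path(dir, "hairpins.bed")
  manifest <- jsonlite::read_json(paste0(px, ".manifest.json"),
                                  simplifyVector = TRUE)
  write.table(data.frame("chr1", manifest$truth$hairpin_start - 1L,
                         manifest$truth$hairpin_end),
              truth_bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  metrics <- file.path(dir, "metrics.json")
  expect_equal(crf_cli(c("eval", "--segments", segs, "--truth",
                         truth_bed, "--out", metrics)), 0L)
  m <- jsonlite::read_json(metrics, simplifyVector = TRUE)
  expect_gte(m$segments$sens, 0.5)
  # fold subcommand on the same FASTA
  bpp <- file.path(dir, "bpp.bedGraph")
  expect_equal(crf_cli(c("fold", "--fasta", paste0(px, ".fa"),
                         "--bpp", bpp)), 0L)
  expect_true(file.exists(bpp))
})
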