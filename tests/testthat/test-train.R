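# fast scorer used to simulate from a known toy CRF
toy_simulator <- function(graph, params, T_, n_examples, seed,
                          symgen = random_symbols) {
  set.seed(seed)
  paths <- enumerate_paths(graph, T_)
  K <- graph$n_states
  offs <- hairpinCRF:::.emission_offsets
  # transition score of each path under m, precomputed as index lists
  edge_ids <- lapply(paths, function(p) {
    steps <- cbind(c(0L, p), c(p, K + 1L))
    vapply(seq_len(nrow(steps)), function(s)
      which(graph$edges$from == steps[s, 1] &
              graph$edges$to == steps[s, 2])[1], integer(1))
  })
  tr_scores <- vapply(edge_ids, function(ids)
    sum(params$m[params$n_em + ids]), numeric(1))
  W <- matrix(params$m[seq_len(params$n_em)], nrow = 35)
  out <- vector("list", n_examples)
  for (e in seq_len(n_examples)) {
    sym <- unclass(symgen(T_, seed + e))
    E <- vapply(seq_len(K), function(k)
      vapply(seq_len(T_), function(t)
        sum(W[offs + sym[t, ], k]), numeric(1)), numeric(T_))
    em_scores <- vapply(paths, function(p)
      sum(E[cbind(seq_len(T_), p)]), numeric(1))
    sc <- em_scores + tr_scores
    pick <- sample.int(length(paths), 1, prob = exp(sc - max(sc)))
    out[[e]] <- labeled_example(
      structure(sym, class = "symbol_sequence"),
      graph$states$label[paths[[pick]]])
  }
  out
}

test_that("fitting recovers a planted symbol bias and is deterministic", {
  g <- toy_graph()
  set.seed(61)
  # planted rule: M-positions prefer symbol 1 in dimension 7, N prefer 4
  make_ex <- function(n) lapply(seq_len(n), function(e) {
    T_ <- 6
    path <- if (e %% 2 == 0) c(1, 2, 3, 3, 3, 3) else c(3, 3, 1, 1, 2, 3)
    sym <- unclass(random_symbols(T_, 6100 + e))
    lab <- g$states$label[path]
    sym[, 7] <- ifelse(lab == "M",
                       sample(c(1L, 4L), T_, TRUE, c(.9, .1)),
                       sample(c(1L, 4L), T_, TRUE, c(.1, .9)))
    labeled_example(structure(sym, class = "symbol_sequence"), lab)
  })
  train <- make_ex(30)
  fit <- crf_fit(train, c = 10, g, training_config(max_iter = 120))
  expect_true(isTRUE(attr(fit, "converged")) || is.numeric(fit$m))
  # objective improved over the zero start
  obj0 <- penalized_objective(crf_params(g), train, 10, g,
                              gradient = FALSE)$value
  expect_gt(attr(fit, "objective"), obj0)
  # held-out accuracy beats chance
  test <- make_ex(20)
  acc <- mean(unlist(lapply(test, function(ex) {
    post <- forward_backward(fit, g, ex$symbols)
    pred <- g$states$label[max.col(post)]
    pred == ex$labels
  })))
  expect_gt(acc, 0.6)
  # bit-identical refit
  fit2 <- crf_fit(train, c = 10, g, training_config(max_iter = 120))
  expect_identical(fit$m, fit2$m)
})

test_that("weaker shrinkage yields larger fitted parameter norms", {
  g <- toy_graph()
  ex <- toy_simulator(g, crf_params(g), T_ = 5, n_examples = 12,
                      seed = 62)
  # add a bias so there is signal to fit
  ex <- lapply(ex, function(e) {
    s <- unclass(e$symbols)
    s[e$labels == "M", 7] <- 1L
    labeled_example(structure(s, class = "symbol_sequence"), e$labels)
  })
  f_small <- crf_fit(ex, c = 0.1, g, training_config(max_iter = 100))
  f_big <- crf_fit(ex, c = 100, g, training_config(max_iter = 100))
  expect_gt(sqrt(sum(f_big$m^2)), sqrt(sum(f_small$m^2)))
})

test_that("fitted model reproduces pairwise log-odds of a known CRF", {
  # a toy CRF that only ever emits 2 symbols per dimension, so its
  # effective parameter count is well below the 2000 training positions
  binary_symbols <- function(T_, seed) {
    set.seed(seed)
    m <- sapply(rep(2, 7), function(k) sample.int(k, T_, replace = TRUE))
    structure(matrix(as.integer(m), T_, 7), class = "symbol_sequence")
  }
  g <- toy_graph()
  set.seed(63)
  truth <- crf_params(g, rnorm(crf_params(g)$J, 0, 1.0))
  T_ <- 6
  n_ex <- 340 # ~2000 labeled positions
  ex <- toy_simulator(g, truth, T_, n_ex, seed = 64,
                      symgen = binary_symbols)
  fit <- crf_fit(ex, c = 100, g, training_config(max_iter = 400))
  # compare log-odds between competing labelings on fresh inputs
  rel_errs <- c()
  for (r in 1:40) {
    sym <- binary_symbols(T_, 6500 + r)
    y1 <- c("M", "L", "N", "N", "N", "N")
    y2 <- c("N", "N", "M", "M", "L", "N")
    lo <- function(p) {
      constrained_log_likelihood(p, labeled_example(sym, y1), g,
                                 gradient = FALSE)$value -
        constrained_log_likelihood(p, labeled_example(sym, y2), g,
                                   gradient = FALSE)$value
    }
    d_true <- lo(truth); d_fit <- lo(fit)
    if (abs(d_true) > 2) rel_errs <- c(rel_errs, abs(d_fit - d_true) /
                                         abs(d_true))
  }
  expect_gt(length(rel_errs), 5)
  expect_lt(median(rel_errs), 0.10)
})

test_that("penalty selection exercises the grid and reports per-candidate F", {
  set.seed(65)
  bundle <- generate_genome(6, 16000, seed = 66)
  cfg <- training_config(penalty_grid = c(0.1, 10), rng_seed = 67,
                         max_iter = 60)
  be <- bundle_examples(bundle, seed = 67)
  g <- build_state_graph()
  sel <- select_penalty(be$examples, g, cfg)
  expect_equal(sel$report$c, c(0.1, 10))
  expect_true(all(is.finite(sel$report$max_f)))
  expect_true(sel$c_best %in% cfg$penalty_grid)
  expect_equal(attr(sel$params_best, "objective"),
               max(attr(sel$params_best, "trace")))
  # split: validation never overlaps training
  expect_length(intersect(sel$split$train, sel$split$validation), 0)
})

test_that("label validation and repair follow the run-length rules", {
  lab <- c(rep("N", 30), rep("F", 20), rep("M", 22), rep("L", 12),
           rep("P", 22), rep("F", 20), rep("N", 30))
  expect_length(validate_labels(lab), 0)
  bad <- c(rep("N", 30), rep("F", 19), rep("M", 30), rep("L", 4),
           rep("P", 22), rep("F", 20), rep("N", 30))
  v <- validate_labels(bad)
  expect_length(v, 3)
  expect_match(v[1], "F-run of 19")
  expect_warning(rep2 <- repair_labels(bad), "repairing")
  expect_length(validate_labels(rep2), 0)
})
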