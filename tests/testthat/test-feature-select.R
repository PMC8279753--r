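test_that("mutual information matches closed forms and is symmetric", {
  y <- rep(c(0L, 1L), each = 10)
  expect_equal(mutual_information(y, y), log(2))      # perfectly informative
  expect_equal(mutual_information(rep(1L, 20), y), 0) # constant feature
  set.seed(3)
  x <- sample(1:3, 20, replace = TRUE)
  expect_equal(mutual_information(x, y), mutual_information(y, x))
  expect_equal(mutual_information(x, y), oracle_mi(x, y))
  expect_error(mutual_information(x, rep(1L, 20)), "degenerate")
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("discretization bins at mean +/- sd and matches the loop oracle", {
  set.seed(7)
  x <- matrix(rnorm(200), 20, 10)
  D <- discretize_columns(x)
  expect_true(all(D %in% 1:3))
  expect_equal(unname(D), unname(oracle_discretize(x)), ignore_attr = TRUE)
  # constant column lands in the middle bin
  x[, 1] <- 5
  expect_true(all(discretize_columns(x)[, 1] == 2L))
})

test_that("first mRMR pick maximizes relevance", {
  set.seed(1)
  y <- rep(c(1L, 0L), each = 15)
  x <- cbind(f1 = rnorm(30), f2 = y + rnorm(30, sd = 0.01), f3 = rnorm(30))
  model <- fit_mrmr(x, y, m = 1)
  expect_equal(model$selected_names[1], "f2")
})

test_that("redundancy penalty prefers independent noise over a duplicate", {
  set.seed(2)
  y <- rep(c(1L, 0L), each = 20)
  dup <- y + rnorm(40, sd = 0.01)
  x <- cbind(f1 = dup, f2 = dup, f3 = rnorm(40))
  model <- fit_mrmr(x, y, m = 2)
  expect_equal(model$selected_names[1], "f1")
  expect_equal(model$selected_names[2], "f3")
  expect_equal(model$selected_names, oracle_mrmr(x, y, 2))
})

test_that("greedy selection matches the exhaustive oracle on random fixtures", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(12:30, 1)
    p <- sample(5:12, 1)
    y <- sample(rep(c(0L, 1L), length.out = n))
    x <- matrix(rnorm(n * p), n, p)
    x[, 1:2] <- x[, 1:2] + y          # plant some relevance
    colnames(x) <- sprintf("f%d", seq_len(p))
    m <- sample(2:min(6, p), 1)
    expect_equal(fit_mrmr(x, y, m = m)$selected_names, oracle_mrmr(x, y, m))
  }
})

test_that("selection recovers planted signal columns", {
  fx <- generate_feature_fixture(60, d_signal = 5, d_noise = 50,
                                 effect_size = 3, seed = 42)
  model <- fit_mrmr(fx, m = 5)
  expect_setequal(model$selected_names, sprintf("sig_%d", 1:5))
})

test_that("selection is invariant to sample order and unselected column order", {
  fx <- generate_feature_fixture(40, 3, 20, effect_size = 2, seed = 6)
  base <- fit_mrmr(fx, m = 4)
  perm <- sample(nrow(fx$x))
  shuffled <- fm_subset(fx, rows = perm)
  expect_equal(fit_mrmr(shuffled, m = 4)$selected_names, base$selected_names)
  # permute only never-selected noise columns
  noise <- setdiff(colnames(fx$x), base$selected_names)
  reordered <- fm_subset(fx, cols = c(base$selected_names, rev(noise)))
  expect_setequal(fit_mrmr(reordered, m = 4)$selected_names,
                  base$selected_names)
})

test_that("apply_selection reduces only the aaindex block, idempotently", {
  fx <- generate_feature_fixture(30, 4, 16, effect_size = 2, seed = 3,
                                 bpf_width = 6)
  model <- fit_mrmr(fx, m = 5)
  sel <- apply_selection(fx, model)
  expect_equal(sum(sel$blocks == "bpf"), 6L)
  expect_equal(sum(sel$blocks == "aaindex"), 5L)
  expect_equal(colnames(sel$x)[sel$blocks == "aaindex"],
               model$selected_names)
  expect_equal(apply_selection(sel, model)$x, sel$x)
  missing_fm <- fm_subset(fx, cols = setdiff(colnames(fx$x),
                                             model$selected_names[1]))
  expect_error(apply_selection(missing_fm, model), model$fit_fingerprint)
})

test_that("selection models survive a JSON round trip", {
  fx <- generate_feature_fixture(30, 3, 12, effect_size = 2, seed = 8)
  model <- fit_mrmr(fx, m = 4)
  path <- tempfile(fileext = ".json")
  write_selection_model(model, path)
  back <- read_selection_model(path)
  expect_equal(back$selected_names, model$selected_names)
  expect_equal(back$m, model$m)
  expect_equal(back$fit_fingerprint, model$fit_fingerprint)
  expect_equal(apply_selection(fx, back)$x, apply_selection(fx, model)$x)
})

test_that("m larger than the feature pool is a parameter error", {
  fx <- generate_feature_fixture(20, 2, 3, effect_size = 1, seed = 1)
  expect_error(fit_mrmr(fx, m = 99), "exceeds")
})
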