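test_that("perturbation vector zeroes the binary block and is uniform elsewhere", {
  set.seed(1)
  v <- make_perturbation_vector(140, 50)
  expect_length(v, 190)
  expect_true(all(v[1:140] == 0))
  expect_true(all(v[141:190] >= 0 & v[141:190] < 1))
  expect_true(all(make_perturbation_vector(5, 0) == 0))
  expect_length(make_perturbation_vector(0, 5), 5)
})

test_that("a = 0 reproduces source rows exactly", {
  fx <- generate_feature_fixture(12, 3, 3, effect_size = 1, seed = 2,
                                 bpf_width = 4)
  aug <- augment_training_set(fx, augmentation_config(a = 0, n_fraction = 1,
                                                      seed = 9))
  pseudo <- aug$source != "-"
  src <- match(aug$source[pseudo], rownames(fx$x))
  expect_equal(unname(aug$x[pseudo, ]), unname(fx$x[src, ]))
})

test_that("pseudosamples obey F_new = F_i * (1 + a V) blockwise", {
  a <- 0.005
  fx <- generate_feature_fixture(20, 4, 4, effect_size = 1, seed = 3,
                                 bpf_width = 6)
  aug <- augment_training_set(fx, augmentation_config(a = a, n_fraction = 2,
                                                      seed = 11))
  pseudo <- which(aug$source != "-")
  src <- match(aug$source[pseudo], rownames(fx$x))
  bpf_cols <- aug$blocks == "bpf"
  aai_cols <- aug$blocks == "aaindex"
  for (i in seq_along(pseudo)) {
    new <- aug$x[pseudo[i], ]
    old <- fx$x[src[i], ]
    # binary block is a bit-identical copy
    expect_identical(unname(new[bpf_cols]), unname(old[bpf_cols]))
    # aaindex entries move away from zero by a relative amount in [0, a)
    ratio <- new[aai_cols] / old[aai_cols]
    expect_true(all(ratio >= 1 & ratio < 1 + a))
    # labels carried over
    expect_equal(aug$labels[pseudo[i]], fx$labels[src[i]])
  }
})

test_that("supremum perturbation of a unit value is 1 + a", {
  # direct formula check: source value 1, V -> 1, a = 0.005 gives 1.005
  expect_equal(1 * (1 + 0.005 * 1), 1.005)
  # and augment_class never exceeds that bound for unit sources
  x <- matrix(1, nrow = 4, ncol = 3,
              dimnames = list(paste0("s", 1:4), paste0("f", 1:3)))
  set.seed(5)
  out <- augment_class(x, augmentation_config(a = 0.005, n_fraction = 50),
                       block_tags = rep("aaindex", 3))
  expect_true(all(out$x >= 1 & out$x < 1.005))
})

test_that("mean relative perturbation converges to a/2", {
  a <- 0.005
  x <- matrix(1, nrow = 1, ncol = 10,
              dimnames = list("s1", paste0("f", 1:10)))
  set.seed(8)
  out <- augment_class(x, augmentation_config(a = a, n_fraction = 1000),
                       block_tags = rep("aaindex", 10))
  rel <- out$x - 1                    # 10,000 draws of a * U(0,1)
  se <- a / sqrt(12 * length(rel))
  expect_lt(abs(mean(rel) - a / 2), 3 * se)
})

test_that("class-wise augmentation preserves counts and class ratio", {
  fx <- generate_feature_fixture(18, 2, 2, effect_size = 1, seed = 4)
  # 9 positive + 9 negative, n_fraction 1 doubles both
  aug <- augment_training_set(fx, augmentation_config(n_fraction = 1,
                                                      seed = 2))
  expect_equal(sum(aug$labels == 1), 18L)
  expect_equal(sum(aug$labels == 0), 18L)
  expect_equal(nrow(aug$x), 36L)
  # n_fraction 0 is a no-op
  same <- augment_training_set(fx, augmentation_config(n_fraction = 0))
  expect_identical(same$x, fx$x)
  # half-up rounding of non-integer pseudocounts: 1.5 * 9 = 13.5 -> 14
  aug15 <- augment_training_set(fx, augmentation_config(n_fraction = 1.5,
                                                        seed = 2))
  expect_equal(sum(aug15$labels == 1) - 9L, 14L)
})

test_that("augmentation is bit-reproducible under a fixed seed", {
  fx <- generate_feature_fixture(14, 3, 3, effect_size = 1, seed = 6)
  cfg <- augmentation_config(n_fraction = 2, seed = 123)
  a1 <- augment_training_set(fx, cfg)
  a2 <- augment_training_set(fx, cfg)
  expect_identical(a1, a2)
})

test_that("degenerate augmentation inputs raise errors", {
  x <- matrix(1, 0, 3)
  expect_error(augment_class(x, augmentation_config(),
                             block_tags = rep("aaindex", 3)), "empty")
  x2 <- matrix(1, 2, 3, dimnames = list(c("a", "b"), NULL))
  expect_error(augment_class(x2, augmentation_config(),
                             block_tags = c("aaindex", "aaindex", "weird")),
               "unknown block tag")
  fx <- generate_feature_fixture(10, 2, 2, effect_size = 1, seed = 1)
  fx$labels <- NULL
  expect_error(augment_training_set(fx, augmentation_config()), "labeled")
})
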