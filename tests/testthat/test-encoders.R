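test_that("binary profile encoding is positional one-hot with X as zeros", {
  v <- encode_bpf(paste0("AC", strrep("X", 5)))
  expect_length(v, 140)
  expect_equal(unname(v[1:20]), c(1, rep(0, 19)))        # A
  expect_equal(unname(v[21:40]), c(0, 1, rep(0, 18)))    # C
  expect_equal(sum(v), 2)                                # X positions all zero
  expect_equal(sum(encode_bpf(strrep("X", 7))), 0)
  expect_error(encode_bpf("FAK"), "shorter")
})

test_that("bpf one-count equals the number of non-X residues among the first k", {
  set.seed(9)
  for (i in 1:20) {
    n_real <- sample(0:7, 1)
    seq <- paste0(paste(sample(aa_alphabet(), n_real, replace = TRUE),
                        collapse = ""),
                  strrep("X", 10 - n_real))
    expect_equal(sum(encode_bpf(seq)), n_real)
  }
})

test_that("aaindex encoding is a position-major table lookup", {
  tab <- aaindex_table()
  expect_equal(dim(tab), c(531L, 20L))
  v <- encode_aaindex(normalize_length("FAKLL", 40))
  expect_length(v, 21240)
  # position 1 is residue F: first 531 entries equal the F column
  expect_equal(unname(v[1:531]), unname(tab[, "F"]))
  # position 3 is K
  expect_equal(unname(v[(2 * 531 + 1):(3 * 531)]), unname(tab[, "K"]))
  # padding positions are zero
  expect_true(all(v[(5 * 531 + 1):21240] == 0))
  expect_equal(sum(encode_aaindex(strrep("X", 12))), 0)
  expect_error(encode_aaindex("FAKLL", l_x = 40), "length")
})

test_that("aaindex encoding is linear in the table values", {
  tab <- aaindex_table()[1:7, , drop = FALSE]
  s <- normalize_length("GIGAVLKV", 10)
  expect_equal(encode_aaindex(s, table = 2 * tab),
               2 * encode_aaindex(s, table = tab))
})

test_that("k-mer matrix has one k-mer per X-free window", {
  M <- build_kmer_matrix(normalize_length(strrep("A", 40), 40))
  expect_equal(dim(M), c(343L, 38L))
  expect_true(all(Matrix::colSums(M) == 1))

  M2 <- build_kmer_matrix("AAAAA")
  expect_equal(dim(M2), c(343L, 3L))
  expect_equal(M2[, 1], M2[, 2])
  expect_equal(as.vector(Matrix::rankMatrix(M2)), 1)

  # X voids the windows it touches
  M3 <- build_kmer_matrix("AAXAA")
  expect_equal(unname(Matrix::colSums(M3)), c(0, 0, 0))
  expect_error(build_kmer_matrix("AC", kmer_config(K = 3)), "shorter")
})

test_that("k-mer row indexing is the base-7 class number", {
  cfg <- kmer_config()
  # DEC: D,E in class 6, C in class 7 -> row (6-1)*49 + (6-1)*7 + (7-1) + 1
  M <- build_kmer_matrix("DEC", cfg)
  expect_equal(unname(which(M[, 1] == 1)), 5 * 49 + 5 * 7 + 6 + 1)
  expect_equal(rownames(M)[which(M[, 1] == 1)], "kmer_667")
})

test_that("svd reduction matches an eigendecomposition oracle", {
  out <- svd_reduce_kmer(build_kmer_matrix("AAAAA"))
  expect_length(out, 343)
  nz <- which(abs(out) > 1e-12)
  expect_length(nz, 1)
  expect_equal(unname(out[nz]), sqrt(3))

  # fixtures drawn from few residue classes so repeated k-mers give the
  # matrix a unique leading singular value (the reduction is only defined
  # up to rotation when singular values tie)
  set.seed(4)
  n_checked <- 0
  for (seq in replicate(10, paste(sample(c("A", "R", "D", "C"), 30,
                                         replace = TRUE), collapse = ""))) {
    M <- build_kmer_matrix(seq)
    d <- svd(as.matrix(M))$d
    if (d[1] - d[2] < 1e-6) next
    expect_lt(sqrt(sum((svd_reduce_kmer(M) - oracle_svd_vector(M))^2)), 1e-8)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 3)
  M <- build_kmer_matrix("GIGAVLKVA")
  expect_equal(svd_reduce_kmer(M * 2.5), 2.5 * svd_reduce_kmer(M))
  expect_error(svd_reduce_kmer(Matrix::Matrix(0, 4, 3, sparse = TRUE)),
               "degenerate")
})

test_that("encode_dataset concatenates blocks in fixed order with tags", {
  ds <- generate_dataset(6, 5, length_range = c(10, 30), seed = 8)
  fm <- encode_dataset(ds, l_x = 40, feature_set = c("bpf", "aaindex", "kmer"))
  expect_equal(as.integer(table(factor(fm$blocks,
                                       c("bpf", "aaindex", "kmer")))),
               c(140L, 21240L, 343L))
  expect_equal(rle(fm$blocks)$values, c("bpf", "aaindex", "kmer"))
  expect_equal(rownames(fm$x), ds$id)
  expect_equal(fm$labels, ds$label)
  # bpf block is 0/1
  expect_true(all(fm_block(fm, "bpf") %in% c(0, 1)))

  solo <- encode_dataset(ds, l_x = 40, feature_set = "bpf")
  expect_equal(ncol(solo$x), 140L)
})

test_that("feature matrix TSV round-trips values, blocks, labels, source", {
  fm <- generate_feature_fixture(8, 3, 4, effect_size = 1, seed = 2,
                                 bpf_width = 2)
  path <- tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$x, fm$x)
  expect_equal(back$blocks, fm$blocks)
  expect_equal(back$labels, fm$labels)
  expect_equal(back$source, fm$source)
})
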