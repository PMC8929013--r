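test_that("dimensionality contracts hold across window lengths", {
  for (lambda in c(5L, 21L, 31L)) {
    seqs <- random_rna(3, lambda, seed = lambda)
    tab <- fit_pskp(seqs[1:2], seqs[3])
    for (s in seqs) {
      expect_length(encode_one_hot(s), 20 * lambda - 16)
      expect_length(encode_kmer(s), 20)
      expect_length(encode_kd(s), 2 * lambda - 1)
      expect_length(encode_ncp(s), 3 * lambda)
      expect_length(encode_pskp(s, tab), 2 * lambda - 1)
      expect_length(encode_psednc(s, psednc_config(lambda_pse = 2)), 18)
    }
    expect_identical(descriptor_dim("ONEHOT", lambda), 20L * lambda - 16L)
  }
  expect_length(encode_one_hot(random_rna(1, 21, 1)), 404)
  expect_length(encode_one_hot(random_rna(1, 31, 1)), 604)
})

test_that("one-hot blocks are indicator vectors in the canonical order", {
  expect_identical(unname(encode_one_hot("A")), c(1, 0, 0, 0))
  expect_identical(unname(encode_one_hot("U")), c(0, 1, 0, 0))
  expect_identical(unname(encode_one_hot("G")), c(0, 0, 0, 1))
  v <- encode_one_hot("AU")
  expect_length(v, 24)
  expect_identical(unname(v[1:8]), c(1, 0, 0, 0, 0, 1, 0, 0))
  di <- v[9:24]
  expect_identical(sum(di), 1)
  expect_identical(names(di)[di == 1], "oh_d1_AU")
  # every 4- or 16-bit block sums to exactly 1
  s <- random_rna(1, 21, seed = 2)
  v <- encode_one_hot(s)
  blocks <- c(split(v[1:84], rep(1:21, each = 4)),
              split(v[85:404], rep(1:20, each = 16)))
  expect_true(all(vapply(blocks, sum, numeric(1)) == 1))
})

test_that("k-mer frequencies count substrings and sum to one per group", {
  v <- encode_kmer("AAAA")
  expect_identical(unname(v[1]), 1)
  expect_identical(unname(v["kmer_AA"]), 1)
  expect_identical(sum(v[1:4] != 0), 1L)
  v <- encode_kmer("AUAU")
  expect_equal(unname(v[c("kmer_A", "kmer_U")]), c(0.5, 0.5))
  expect_equal(unname(v[c("kmer_AU", "kmer_UA")]), c(2 / 3, 1 / 3))
  for (s in random_rna(5, 21, seed = 3)) {
    v <- encode_kmer(s)
    expect_equal(sum(v[1:4]), 1)
    expect_equal(sum(v[5:20]), 1)
  }
  expect_error(encode_kmer("A"), "length >= 2")
})

test_that("k-density is the prefix density of the observed symbol", {
  expect_equal(unname(encode_kd("AAAA")[1:4]), rep(1, 4))
  expect_equal(unname(encode_kd("AUAU")[1:4]), c(1, 1 / 2, 2 / 3, 1 / 2))
  expect_equal(unname(encode_kd("GACU")[1:4]), c(1, 1 / 2, 1 / 3, 1 / 4))
  for (s in random_rna(5, 21, seed = 4)) {
    v <- encode_kd(s)
    expect_true(all(v > 0 & v <= 1))
  }
  expect_equal(unname(encode_kd(strrep("C", 8))), rep(1, 15))
})

test_that("NCP reproduces the chemical-property table", {
  expect_identical(unname(encode_ncp("A")), c(1, 1, 1))
  expect_identical(unname(encode_ncp("U")), c(0, 0, 1))
  expect_identical(unname(encode_ncp("C")), c(0, 1, 0))
  expect_identical(unname(encode_ncp("G")), c(1, 0, 0))
  expect_identical(unname(encode_ncp("AU")), c(1, 1, 1, 0, 0, 1))
})

test_that("propensity tables are frequency differences with zero row sums", {
  s <- random_rna(6, 9, seed = 5, center_u = TRUE)
  tab0 <- fit_pskp(s, s)
  expect_true(all(tab0$mono == 0) && all(tab0$di == 0))
  expect_equal(unname(encode_pskp(s[1], tab0)), rep(0, 17))

  tab <- fit_pskp(c("AU", "AU"), c("AU", "GU"))
  expect_equal(tab$mono["p1", "A"], 0.5)
  expect_equal(tab$mono["p1", "G"], -0.5)
  expect_equal(tab$mono["p2", "U"], 0)
  expect_equal(unname(encode_pskp("AU", tab)[1:2]), c(0.5, 0))

  pos <- random_rna(15, 21, seed = 6)
  neg <- random_rna(15, 21, seed = 7)
  tab <- fit_pskp(pos, neg)
  expect_true(all(abs(rowSums(tab$mono)) < 1e-12))
  expect_true(all(abs(rowSums(tab$di)) < 1e-12))
  expect_true(all(tab$mono >= -1 & tab$mono <= 1))
  expect_error(fit_pskp(c("AU"), c("AUG")), "heterogeneous")
})

test_that("PseDNC is a normalized composition with correlation tiers", {
  cfg <- psednc_config()
  # standardized properties: mean 0, population variance 1
  expect_true(all(abs(colMeans(cfg$properties)) < 1e-9))
  expect_true(all(abs(colMeans(cfg$properties^2) - 1) < 1e-9))

  s <- random_rna(1, 21, seed = 8)
  v0 <- encode_psednc(s, psednc_config(lambda_pse = 0))
  expect_length(v0, 16)
  expect_equal(sum(v0), 1)
  expect_equal(unname(v0), unname(encode_kmer(s)[5:20]))

  for (lp in c(0, 2, 5)) {
    v <- encode_psednc(s, psednc_config(lambda_pse = lp, w = 0.5))
    expect_length(v, 16 + lp)
    expect_true(all(v >= 0))
    expect_equal(sum(v), 1)
  }
  # homopolymer: all correlation tiers vanish
  h <- strrep("A", 12)
  expect_equal(unname(encode_psednc(h, psednc_config(lambda_pse = 3))[17:19]),
               rep(0, 3))
  expect_error(encode_psednc("ACGU", psednc_config(lambda_pse = 3)),
               "lambda_pse")
})

test_that("each encoder matches an independent brute-force oracle", {
  seqs <- random_rna(25, 21, seed = 9)
  pos <- random_rna(10, 21, seed = 10)
  neg <- random_rna(10, 21, seed = 11)
  tab <- fit_pskp(pos, neg)
  cfg <- psednc_config(lambda_pse = 3, w = 0.2)
  for (s in seqs) {
    expect_equal(unname(encode_one_hot(s)), oracle_onehot(s))
    expect_equal(unname(encode_kmer(s)), oracle_kmer(s))
    expect_equal(unname(encode_kd(s)), oracle_kd(s))
    expect_equal(unname(encode_ncp(s)), oracle_ncp(s))
    expect_equal(unname(encode_pskp(s, tab)), oracle_pskp(s, pos, neg))
    expect_equal(unname(encode_psednc(s, cfg)),
                 oracle_psednc(s, 3, 0.2, cfg$properties))
  }
})

test_that("dataset encoding preserves order, labels and shape", {
  ds <- separable_dataset(n_per_class = 2, lambda = 21)
  x <- encode_dataset(ds, "KMER")
  expect_identical(dim(x), c(4L, 20L))
  expect_identical(attr(x, "labels"), ds$labels)
  expect_identical(rownames(x), names(ds$sequences))
  expect_identical(dim(encode_dataset(ds, "ONEHOT")), c(4L, 404L))
  expect_error(encode_dataset(ds, "PSKP"), "propensity table")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(x, tsv)
  x2 <- read_feature_tsv(tsv)
  expect_equal(unclass(x2)[, ], unclass(x)[, ], ignore_attr = TRUE)
  expect_identical(attr(x2, "labels"), ds$labels)
})
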