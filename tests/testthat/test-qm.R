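test_that("position frequencies tabulate counts per core position", {
  pfm <- count_position_frequencies("AAAAAAAAA")
  f <- attr(pfm, "frequencies")
  expect_equal(unname(f["A", ]), rep(1, 9))
  expect_equal(sum(f), 9)  # everything else zero

  pfm2 <- count_position_frequencies(c("AAAAAAAAA", "CCCCCCCCC"))
  f2 <- attr(pfm2, "frequencies")
  expect_equal(unname(f2["A", ]), rep(0.5, 9))
  expect_equal(unname(f2["C", ]), rep(0.5, 9))
  expect_equal(attr(pfm2, "n"), 2L)
  # every position accounts for every peptide
  expect_equal(unname(colSums(pfm2)), rep(2L, 9))
  # duplicates counted with multiplicity
  pfm3 <- count_position_frequencies(rep("AAAAAAAAA", 3))
  expect_equal(attr(pfm3, "n"), 3L)
  expect_equal(unname(pfm3["A", "p1"]), 3L)
})

test_that("invalid training input is rejected with the offender named", {
  expect_error(count_position_frequencies(character(0)), "empty")
  expect_error(count_position_frequencies(c("AAAAAAAAA", "SHORT")), "SHORT")
  expect_error(count_position_frequencies("AAAAAAAAX"), "AAAAAAAAX")
})

test_that("mean normalization uses global statistics over all 180 cells", {
  # training composition mirroring the published p4 description: N = 105,
  # global count extremes 27 and 0; p4 column carries counts
  # 14/14/14 (A, R, L), 5 (D), 1 (N), 2 (E)
  counts <- matrix(0L, 20, 9, dimnames = list(AA, paste0("p", 1:9)))
  counts["A", -4] <- 27L
  counts["R", -4] <- 27L
  counts["N", -4] <- 27L
  counts["D", -4] <- 24L
  counts[c("A", "R", "L"), 4] <- 14L
  counts["D", 4] <- 5L
  counts["N", 4] <- 1L
  counts["E", 4] <- 2L
  counts["Q", 4] <- 27L
  counts["G", 4] <- 27L
  counts["H", 4] <- 1L
  stopifnot(all(colSums(counts) == 105L), max(counts) == 27L)
  qm <- mean_normalize(pfm_from_counts(counts), "binder")
  expect_equal(round_half_up(qm["A", "p4"]), 0.324)
  expect_equal(round_half_up(qm["D", "p4"]), -0.009)
  expect_equal(round_half_up(qm["E", "p4"]), -0.120)
  expect_equal(round_half_up(qm["N", "p4"]), -0.157)
  expect_equal(round_half_up(qm["C", "p4"]), -0.194)  # zero count
  # equal counts give equal coefficients
  expect_length(unique(qm[c("A", "R", "L"), "p4"]), 1L)
  # exact closed form: (c - N/20) / (cmax - cmin)
  expect_equal(unname(qm["A", "p4"]), (14 - 5.25) / 27)
})

test_that("degenerate frequency matrices are an explicit error", {
  counts <- matrix(5L, 20, 9)
  expect_error(mean_normalize(pfm_from_counts(counts)), "degenerate")
})

test_that("single-sequence closed form and QM invariants hold", {
  qm <- derive_qm("FFFFFFFFF", "binder")
  expect_equal(unname(qm["F", ]), rep(0.95, 9))
  expect_equal(unname(qm["A", ]), rep(-0.05, 9))

  for (seed in 1:5) {
    q <- derive_qm(random_nonamers(50, seed), "binder")
    expect_lt(abs(sum(q)), 1e-9)          # mean subtraction
    expect_true(all(q >= -1 & q <= 1))    # normalization range
  }
})

test_that("integer training counts are recoverable from a derived QM", {
  set.seed(42)
  for (i in 1:5) {
    nonamers <- random_nonamers(40, seed = 100 + i)
    pfm <- count_position_frequencies(nonamers)
    qm <- derive_qm(nonamers, "binder")
    rng <- range(unclass(pfm))
    expect_identical(qm_counts(qm, n = 40, count_range = rng),
                     matrix(as.integer(unclass(pfm)), 20, 9,
                            dimnames = dimnames(unclass(pfm))))
  }
})

test_that("a planted anchor dominates the derived matrix", {
  set <- generate_binder_set(500, anchors = c(p1 = "F"), anchor_prob = 0.8,
                             seed = 11)
  qm <- derive_qm(set, "binder")
  expect_equal(which.max(unclass(qm)),
               which(rownames(qm) == "F"))  # F at p1 is cell (14, 1)
  # brute-force frequency check of the same cell
  first <- substr(set, 1, 1)
  expect_equal(unname(unclass(count_position_frequencies(set))["F", "p1"]),
               sum(first == "F"))
})

test_that("published matrices match their printed cells and sum near zero", {
  expect_equal(unname(QB["F", "p1"]), 0.806)
  expect_equal(unname(QB["L", "p2"]), 0.694)
  expect_equal(unname(QNB["S", "p6"]), 0.672)
  expect_equal(unname(QNB["G", "p9"]), 0.609)
  expect_equal(attr(QB, "role"), "binder")
  expect_equal(attr(QNB, "role"), "non-binder")
  # printed at 3 d.p., so the global sum is zero within rounding slack
  expect_lte(abs(sum(QB)), 0.09)
  expect_lte(abs(sum(QNB)), 0.09)
  # the published binder matrix encodes the stated p4 training composition
  counts <- qm_counts(QB, n = 105, count_range = c(0, 27))
  expect_equal(unname(counts[c("D", "N", "E"), "p4"]), c(5L, 1L, 2L))
  expect_equal(unname(counts[c("A", "R", "L"), "p4"]), rep(14L, 3))
  expect_error(published_qm("foo"))
})

test_that("QM TSV round trip preserves values, order and role", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_qm(QNB, path)
  back <- read_qm(path)
  expect_equal(unclass(back), unclass(QNB), ignore_attr = TRUE)
  expect_equal(attr(back, "role"), "non-binder")

  qm <- derive_qm(random_nonamers(30, 1), "binder")
  write_qm(qm, path)
  expect_equal(unclass(read_qm(path)), round_half_up(unclass(qm), 3),
               ignore_attr = TRUE)
})

test_that("malformed QM files are rejected", {
  good <- readLines(system.file("extdata", "qm_drb1_0301_binder.tsv",
                                package = "logomhc"))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(good[-5], p)  # drop one amino-acid row -> 19 rows
  expect_error(read_qm(p), "20")
  bad <- sub("0.806", "1.5", good, fixed = TRUE)
  writeLines(bad, p)
  expect_error(read_qm(p), "\\[-1, 1\\]")
  writeLines(sub("^A\t", "Z\t", good), p)
  expect_error(read_qm(p), "amino-acid")
  expect_error(read_qm("/nonexistent/qm.tsv"), "no such file")
})
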