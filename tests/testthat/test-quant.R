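mk_reads <- function(inserts) data.table::data.table(insert = inserts)

test_that("miRNA counting uses exact 18-nt prefix identity", {
  mirnas <- data.frame(
    id = c("mir-a", "mir-b"),
    sequence = c("ACGUACGUACGUACGUACGUAC", "GGCAUGGCAUGGCAUGGCAUGG"),
    stringsAsFactors = FALSE
  )
  p <- substr(mirnas$sequence[1], 1, 18)
  reads <- mk_reads(c(
    p,                                   # exact 18-nt read
    paste0(p, "AAAAAA"),                 # 24 nt with tail: still assigned
    paste0("G", substr(p, 2, 18))        # position-1 mismatch: unassigned
  ))
  counts <- count_mirna_reads(reads, mirnas)
  expect_equal(unname(counts["mir-a"]), 2L)
  expect_equal(unname(counts["mir-b"]), 0L)
  rep_ <- attr(counts, "report")
  expect_equal(rep_$n_unassigned, 1L)

  # single mismatch inside the prefix breaks assignment
  mm <- paste0(substr(p, 1, 2), "X", substr(p, 4, 18))
  expect_equal(sum(count_mirna_reads(mk_reads(mm), mirnas)), 0L)

  short <- rbind(mirnas, data.frame(id = "tiny", sequence = "ACGUACGUACG"))
  expect_warning(count_mirna_reads(reads, short), "tiny")
})

test_that("ambiguous prefixes count once per matching miRNA", {
  shared <- "ACGUACGUACGUACGUAC"
  mirnas <- data.frame(id = c("m1", "m2"),
                       sequence = c(paste0(shared, "AAA"),
                                    paste0(shared, "GGG")))
  counts <- count_mirna_reads(mk_reads(paste0(shared, "CCCC")), mirnas)
  expect_equal(as.integer(counts), c(1L, 1L))
  expect_equal(attr(counts, "report")$n_ambiguous, 1L)
})

test_that("length distributions are normalized over 18-26 nt", {
  m <- "ACGUACGUACGUACGUACGUAC"
  p <- substr(m, 1, 18)
  reads <- mk_reads(c(rep(strrep(substr(paste0(p, "AAAA"), 1, 22), 1), 80),
                      rep(substr(paste0(p, "AAAAA"), 1, 23), 20)))
  fr <- length_distribution(reads, m)
  expect_equal(unname(fr["22"]), 0.8)
  expect_equal(unname(fr["23"]), 0.2)
  expect_equal(sum(fr), 1)

  # 27-nt read is excluded from the distribution
  reads27 <- mk_reads(paste0(p, strrep("A", 9)))
  fr <- length_distribution(reads27, m)
  expect_equal(sum(fr), 0)
  expect_equal(attr(fr, "n"), 0L)

  empty <- length_distribution(mk_reads(character(0)), m)
  expect_true(all(empty == 0))
})

test_that("RPM normalization conserves column totals", {
  m <- matrix(c(10L, 990L, 5L, 15L), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  r <- rpm_normalize(m)
  expect_equal(r["g1", "s1"], 1e4)
  expect_equal(unname(colSums(r)), c(1e6, 1e6))
  m0 <- m; m0[, 2] <- 0L
  expect_error(rpm_normalize(m0), "s2")
})

test_that("size factors follow the median-of-ratios definition", {
  # proportional two-sample case: B = 2A genewise
  a <- c(10, 100, 40, 7)
  m <- cbind(s1 = a, s2 = 2 * a)
  rownames(m) <- paste0("g", 1:4)
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  ident <- cbind(s1 = a, s2 = a)
  expect_equal(unname(size_factors(ident)), c(1, 1))

  # random matrices match the direct-formula computation
  withr::with_seed(31, {
    for (i in 1:20) {
      mm <- matrix(rpois(200, 50), 50, 4,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
      sf <- size_factors(mm)
      geo <- apply(mm, 1, function(x) prod(x)^(1 / length(x)))
      keep <- geo > 0
      ref <- apply(mm[keep, ], 2, function(x) median(x / geo[keep]))
      expect_equal(sf, ref, tolerance = 1e-9)
    }
  })

  zero <- matrix(c(0L, 5L, 3L, 0L), 2)
  expect_error(size_factors(zero), "no gene")
})

test_that("size factors agree with the reference implementation", {
  skip_if_not_installed("DESeq2")
  withr::with_seed(32, {
    m <- matrix(rnbinom(300, mu = 100, size = 5), 75, 4,
                dimnames = list(paste0("g", 1:75), paste0("s", 1:4)))
  })
  # the reference interpolates the median on the log scale; identical on
  # odd usable-gene counts, within interpolation error otherwise
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-3)
})

test_that("differential applies the baseMean filters and log2 fold change", {
  withr::with_seed(33, {
    base <- c(g_low = 150, g_mid = 100, g_hi = 5000)
    counts <- sapply(1:6, function(s) round(base * runif(3, 0.98, 1.02)))
    rownames(counts) <- names(base)
    colnames(counts) <- c(paste0("c", 1:3), paste0("k", 1:3))
  })
  cond <- setNames(rep(c("control", "ko"), each = 3), colnames(counts))
  res_mi <- differential(counts, cond, "mirna")
  expect_false(res_mi$kept[res_mi$gene == "g_low"])   # baseMean < 200
  res_mr <- differential(counts, cond, "mrna")
  expect_true(res_mr$kept[res_mr$gene == "g_mid"])    # boundary kept
  expect_true(res_mr$kept[res_mr$gene == "g_low"])    # 150 >= 100

  # doubling: log2fc ~ 1 at large counts
  counts2 <- cbind(matrix(1000L, 2, 3), matrix(2000L, 2, 3))
  dimnames(counts2) <- list(c("a", "b"),
                            c(paste0("c", 1:3), paste0("k", 1:3)))
  res2 <- differential(counts2, cond, "mrna")
  # size-factor normalization absorbs a global doubling, so plant the
  # change in one gene only
  counts3 <- counts2
  counts3["a", 4:6] <- 1000L
  res3 <- differential(counts3, cond, "mrna")
  expect_equal(res3$log2fc[res3$gene == "b"] - res3$log2fc[res3$gene == "a"],
               1, tolerance = 0.05)

  expect_error(differential(counts2, setNames(rep("ko", 6),
                                              colnames(counts2)), "mrna"),
               "both conditions")
})

test_that("planted knockout elevation is recovered from simulated counts", {
  mirnas <- data.frame(id = sprintf("m%02d", 1:40))
  hits <- 0L
  reps <- 40L
  withr::with_seed(34, {
    for (i in seq_len(reps)) {
      sim <- sim_mirna_counts(mirnas, "m01", trigger_fold = 4)
      res <- differential(sim$counts, sim$condition_of, "mirna")
      est <- 2^res$log2fc[res$gene == "m01"]
      if (abs(est - 4) / 4 < 0.25) hits <- hits + 1L
    }
  })
  expect_gte(hits / reps, 0.9)
})
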