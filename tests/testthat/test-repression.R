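test_that("seed-match prediction finds canonical UTR sites only", {
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  seed_rc <- reverse_complement(substr(m, 2, 8))  # matches positions 2-8
  utr_bg <- strrep("CCCCCAAA", 20)
  tx <- data.frame(
    id = c("t8", "t7m8", "t7a1", "tnone", "tcds"),
    sequence = c(
      paste0(utr_bg, paste0(seed_rc, "A"), utr_bg),
      paste0(utr_bg, paste0(seed_rc, "G"), utr_bg),
      paste0(utr_bg, paste0(reverse_complement(substr(m, 2, 7)), "A"),
             utr_bg),
      paste0(utr_bg, utr_bg),
      paste0(paste0(seed_rc, "A"), utr_bg, utr_bg)  # site in CDS only
    ),
    stringsAsFactors = FALSE
  )
  tx$cds_end <- c(0L, 0L, 0L, 0L, 170L)
  # place UTR start after the CDS-located site for tcds
  out <- predict_seed_targets(m, tx)
  expect_setequal(out$transcript_id, c("t8", "t7m8", "t7a1"))
  expect_equal(out$site_class[out$transcript_id == "t8"], "8mer")
  expect_equal(out$site_class[out$transcript_id == "t7m8"], "7mer-m8")
  expect_equal(out$site_class[out$transcript_id == "t7a1"], "7mer-A1")

  tx$cds_end[1] <- NA
  expect_warning(predict_seed_targets(m, tx), "without UTR annotation")
})

test_that("seed-site prediction is position-independent", {
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  site <- paste0(reverse_complement(substr(m, 2, 8)), "A")
  withr::with_seed(45, pad <- random_rna(3, 120))
  # the same UTR content shifted behind a longer CDS gives the same call
  tx <- data.frame(
    id = c("short_cds", "long_cds"),
    sequence = c(paste0(pad[1], site, pad[2]),
                 paste0(pad[3], pad[1], site, pad[2])),
    cds_end = c(nchar(pad[1]) - 20L, nchar(pad[3]) + nchar(pad[1]) - 20L),
    stringsAsFactors = FALSE
  )
  out <- predict_seed_targets(m, tx)
  expect_setequal(out$transcript_id, c("short_cds", "long_cds"))
  expect_equal(unique(out$site_class), "8mer")
})

test_that("target sets are disjoint where required", {
  sets <- build_target_sets(predicted = c("a", "b", "c"),
                            conserved = c("b", "z"),
                            clash = c("b", "d"),
                            universe = letters[1:6])
  expect_equal(sets$conserved_predicted, "b")
  expect_equal(sets$overlap, "b")
  expect_setequal(sets$non_targets, c("e", "f"))
  expect_length(intersect(sets$non_targets, sets$all_predicted), 0)
  expect_length(intersect(sets$non_targets, sets$clash_targets), 0)
})

test_that("cumulative fold-change curves are proper CDFs that detect shifts", {
  withr::with_seed(41, {
    genes <- sprintf("g%04d", 1:1200)
    targets <- genes[1:200]
    lfc <- rnorm(1200, 0, 0.4)
    lfc[1:200] <- lfc[1:200] - 0.3
    diff <- data.frame(gene = genes, baseMean = 500, log2fc = lfc,
                       kept = TRUE)
  })
  sets <- build_target_sets(targets, character(0), character(0), genes)
  cfc <- cumulative_fold_change(diff, sets)
  vals <- attr(cfc, "values")
  F_t <- ecdf(vals$all_predicted)
  F_n <- ecdf(vals$non_targets)
  qs <- seq(-0.8, 0.8, by = 0.1)
  expect_true(all(F_t(qs) >= F_n(qs)))    # target curve left-shifted
  expect_lt(cfc$median_log2fc[cfc$set == "all_predicted"],
            cfc$median_log2fc[cfc$set == "non_targets"])
  # CDF endpoints
  expect_equal(F_t(-Inf), 0)
  expect_equal(F_t(Inf), 1)
  # small sets are flagged
  tiny <- build_target_sets(genes[1:2], character(0), character(0), genes)
  expect_true(cumulative_fold_change(diff, tiny)$low_n[1])
})

test_that("exact Mann-Whitney reproduces hand-enumerated cases", {
  res <- mann_whitney_two_sided(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 1 / 3)   # 2 of the C(4,2)=6 assignments
  expect_equal(res$method, "exact")

  same <- mann_whitney_two_sided(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
})

test_that("exact path equals independent subset enumeration with ties", {
  withr::with_seed(42, {
    for (i in 1:60) {
      n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
      x <- sample(1:6, n1, replace = TRUE)   # ties likely
      y <- sample(1:6, n2, replace = TRUE)
      mine <- mann_whitney_two_sided(x, y)
      ref <- oracle_mw_exact(x, y)
      expect_equal(mine$U, ref$U, info = i)
      expect_equal(mine$p_value, ref$p_value, tolerance = 1e-12, info = i)
    }
  })
})

test_that("normal approximation agrees with the reference implementation", {
  withr::with_seed(43, {
    for (i in 1:20) {
      x <- rnorm(30); y <- rnorm(40, 0.3)
      mine <- mann_whitney_two_sided(x, y)
      ref <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)
      expect_equal(mine$method, "normal")
      expect_equal(mine$U, unname(ref$statistic))
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
    }
  })
})

test_that("organ-normalized correlation recovers exact relationships", {
  organs <- c("head", "gut", "muscle")
  mk <- function(vals) {
    m <- cbind(whole_body = vals, head = 1, gut = 1, muscle = 1)
    rownames(m) <- paste0("e", seq_along(vals))
    m
  }
  # trigger = -2 * mirna + 10 on the normalized scale: r = -1
  mv <- c(1, 2, 3, 4, 5)
  tv <- 10 - 2 * mv
  mm <- mk(mv); tm <- mk(tv)
  rownames(tm) <- paste0("t", 1:5)
  pairs <- data.frame(mirna_id = rownames(mm), transcript_id = rownames(tm))
  res <- organ_normalized_correlation(mm, tm, pairs)
  expect_equal(res$r, -1, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-6)

  # direct-formula check on random values
  withr::with_seed(44, { mv <- runif(5, 1, 9); tv <- runif(5, 1, 9) })
  res <- organ_normalized_correlation(mk(mv), {
    t2 <- mk(tv); rownames(t2) <- paste0("t", 1:5); t2
  }, data.frame(mirna_id = paste0("e", 1:5),
                transcript_id = paste0("t", 1:5)))
  r_ref <- sum((mv - mean(mv)) * (tv - mean(tv))) /
    sqrt(sum((mv - mean(mv))^2) * sum((tv - mean(tv))^2))
  expect_equal(res$r, r_ref, tolerance = 1e-12)

  const <- mk(rep(3, 5)); rownames(const) <- paste0("t", 1:5)
  expect_error(
    organ_normalized_correlation(mk(mv), const,
                                 data.frame(mirna_id = paste0("e", 1:5),
                                            transcript_id = paste0("t", 1:5))),
    "zero variance")
})
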