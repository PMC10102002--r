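cfg <- screen_config()

mk_mirnas <- function() data.frame(
  id = c("mir-001", "mir-002"),
  sequence = c("ACGUACGUGGCCAUAUGCACGU",        # 22 nt
               "GGAUCAUCGAUCGGAUUACAGCA"),      # 23 nt
  stringsAsFactors = FALSE
)

test_that("k-mer index covers every occurrence", {
  tx <- data.frame(id = "t1", sequence = paste(rep("ACGU", 5), collapse = ""))
  idx <- build_kmer_index(tx, k = 12)
  expect_equal(nrow(idx$occurrences), 20 - 12 + 1)   # L - k + 1
  expect_equal(nrow(map_fragment("GGGGGGGGGGGG", idx)), 0L)

  tx2 <- data.frame(id = c("t1", "t2"),
                    sequence = c(paste0("AAAA", strrep("CGUA", 4)),
                                 paste0(strrep("CGUA", 4), "GGGG")))
  idx2 <- build_kmer_index(tx2, k = 12)
  hits <- map_fragment(substr(strrep("CGUA", 4), 1, 12), idx2)
  expect_setequal(hits$transcript_id, c("t1", "t2"))

  expect_warning(build_kmer_index(data.frame(id = "s", sequence = "ACGU")),
                 "shorter than k")
})

test_that("fragments map by exact match only", {
  withr::with_seed(21, tx <- data.frame(id = "t1",
                                        sequence = random_rna(1, 400)))
  idx <- build_kmer_index(tx)
  frag <- substr(tx$sequence, 101, 130)
  hit <- map_fragment(frag, idx)
  expect_equal(hit$start, 100L)         # 0-based
  expect_equal(hit$end, 130L)
  mism <- paste0("A", substr(frag, 2, 30))
  if (mism != frag) expect_equal(nrow(map_fragment(mism, idx)), 0L)
})

test_that("chimeras split into miRNA arm and fragment at either end", {
  mirnas <- mk_mirnas()
  withr::with_seed(22, frag <- random_rna(1, 30))
  s1 <- split_chimera(paste0(mirnas$sequence[1], frag), mirnas)
  expect_equal(s1$mirna_id, "mir-001")
  expect_equal(s1$order, "mirna_first")
  expect_equal(s1$fragment, frag)
  expect_equal(s1$mirna_span, c(0L, 22L))

  s2 <- split_chimera(paste0(frag, mirnas$sequence[2]), mirnas)
  expect_equal(s2$mirna_id, "mir-002")
  expect_equal(s2$order, "mirna_last")
  expect_equal(s2$fragment, frag)

  withr::with_seed(23, noise <- random_rna(1, 52))
  expect_null(split_chimera(noise, mirnas))
  # fragment below the minimum is not a usable split
  expect_null(split_chimera(paste0(mirnas$sequence[1],
                                   substr(frag, 1, 8)), mirnas))
})

test_that("vectorized splitting agrees with the per-read contract", {
  mirnas <- mk_mirnas()
  withr::with_seed(24, {
    frags <- random_rna(30, 28)
    inserts <- c(paste0(mirnas$sequence[1], frags[1:10]),
                 paste0(frags[11:20], mirnas$sequence[2]),
                 random_rna(10, 50))
  })
  vec <- tdmdscreen:::.split_chimeras(inserts, mirnas, cfg)
  for (i in seq_along(inserts)) {
    single <- split_chimera(inserts[i], mirnas, cfg)
    row <- vec[vec$idx == i]
    if (is.null(single)) {
      expect_equal(nrow(row), 0L, info = i)
    } else {
      expect_equal(row$mirna_id, single$mirna_id, info = i)
      expect_equal(row$order, single$order, info = i)
      expect_equal(row$fragment, single$fragment, info = i)
    }
  }
})

test_that("3' extension is clamped at the transcript end", {
  ext <- extend_target_3prime(100L, 130L, 1000L)
  expect_equal(ext$end, 155L)
  expect_equal(ext$start, 100L)
  expect_equal(extend_target_3prime(100L, 130L, 140L)$end, 140L)
  expect_equal(extend_target_3prime(100L, 130L, 130L)$end, 130L)
})

test_that("site aggregation merges nearby sites and computes RPM/enrichment", {
  recs <- data.frame(
    mirna_id = "mir-001", transcript_id = "t1",
    site_start = c(100L, 104L, 100L), site_end = c(155L, 160L, 155L),
    read_count = c(80L, 40L, 120L),
    library_id = c("c1", "c1", "k1"), ambiguous = FALSE
  )
  cond <- c(c1 = "control", k1 = "ko")
  totals <- c(c1 = 1e6, k1 = 1e6)
  out <- aggregate_hybrids(recs, cond, totals)
  expect_equal(nrow(out), 1L)                      # merged
  expect_equal(out$site_start, 100L)
  expect_equal(out$site_end, 160L)
  expect_equal(out$control_count, 120L)
  expect_equal(out$ko_count, 120L)
  expect_equal(out$control_rpm, 120)
  # RPM formula: 240 reads over 2e6 -> 120 RPM
  tot2 <- c(c1 = 2e6, k1 = 2e6)
  rec2 <- recs; rec2$read_count <- c(120L, 120L, 240L)
  out2 <- aggregate_hybrids(rec2, cond, tot2)
  expect_equal(out2$control_rpm, 120)
  # fold change with 0.1 pseudocount: (120.1)/(20.1)
  rec3 <- data.frame(mirna_id = "m", transcript_id = "t",
                     site_start = 0L, site_end = 50L,
                     read_count = c(20L, 120L),
                     library_id = c("c1", "k1"), ambiguous = FALSE)
  out3 <- aggregate_hybrids(rec3, cond, totals)
  expect_equal(out3$fold_change, 120.1 / 20.1, tolerance = 1e-12)

  expect_error(aggregate_hybrids(
    data.frame(mirna_id = "m", transcript_id = "t", site_start = 0L,
               site_end = 10L, read_count = 1L, library_id = "zz",
               ambiguous = FALSE), cond, totals),
    "without condition mapping")
})

test_that("aggregation is order-independent and distance-sensitive", {
  withr::with_seed(25, {
    recs <- data.frame(
      mirna_id = sample(c("m1", "m2"), 50, TRUE),
      transcript_id = sample(c("t1", "t2"), 50, TRUE),
      site_start = sample(c(100L, 105L, 300L), 50, TRUE),
      read_count = sample(1:20, 50, TRUE),
      library_id = sample(c("c1", "k1"), 50, TRUE),
      ambiguous = FALSE
    )
    recs$site_end <- recs$site_start + 55L
  })
  cond <- c(c1 = "control", k1 = "ko")
  totals <- c(c1 = 5e5, k1 = 5e5)
  a <- aggregate_hybrids(recs, cond, totals)
  b <- aggregate_hybrids(recs[sample(nrow(recs)), ], cond, totals)
  expect_equal(a, b)
  # sites 100/105 merge (within 10 nt); 300 stays separate
  per_group <- table(a$mirna_id, a$transcript_id)
  expect_true(all(per_group[per_group > 0] <= 2))
})

test_that("planted exact chimeras are fully recovered per library", {
  mirnas <- mk_mirnas()
  withr::with_seed(26, {
    tx <- data.frame(id = c("t1", "t2"), gene = c("g1", "g2"),
                     sequence = random_rna(2, 600), cds_end = 300L)
    frag1 <- substr(tx$sequence[1], 401, 430)
    frag2 <- substr(tx$sequence[2], 351, 378)
    reads <- c(replicate(25, paste0(mirnas$sequence[1], frag1)),
               replicate(15, paste0(frag2, mirnas$sequence[2])),
               random_rna(60, 40))
  })
  libs <- list(lib1 = data.table::data.table(insert = reads))
  called <- call_hybrids(libs, mirnas, tx, cfg)
  rec <- called$records
  expect_equal(sum(rec$read_count), 40L)   # recall 1.0 by construction
  r1 <- rec[rec$mirna_id == "mir-001"]
  expect_equal(r1$site_start, 400L)
  expect_equal(r1$site_end, 455L)          # +25 extension
  expect_equal(r1$read_count, 25L)
  expect_equal(rec[rec$mirna_id == "mir-002"]$read_count, 15L)
  # conservation: hybrid reads never exceed clean reads
  expect_lte(called$stats$lib1$n_hybrid, called$stats$lib1$n_clean)
})
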