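.RNA <- c("A", "C", "G", "U")
.COMP <- c(A = "U", C = "G", G = "C", U = "A")

# n random RNA strings of length len (vectorized)
.rand_seq <- function(n, len, alphabet = .RNA) {
  if (n == 0L) return(character(0))
  maxlen <- max(len)
  cols <- replicate(maxlen, sample(alphabet, n, replace = TRUE),
                    simplify = FALSE)
  full <- do.call(paste0, cols)
  substr(full, 1L, len)
}

#' Generate a synthetic mature-miRNA set
#'
#' Lengths are drawn from 21-23 nt with uniform random bases; ids and
#' 18-nt prefixes are unique; output is deterministic given the seed.
#'
#' @param n number of miRNAs.
#' @param seed integer RNG seed.
#' @param lengths candidate mature lengths (default 21:23).
#' @return data.frame with `id`, `sequence`, `arm` (all `"guide"`).
#' @export
gen_mirnome <- function(n, seed, lengths = 21:23) {
  if (n == 0L)
    return(data.frame(id = character(0), sequence = character(0),
                      arm = character(0), stringsAsFactors = FALSE))
  with_seed(seed, {
    seqs <- .rand_seq(n, sample(lengths, n, replace = TRUE))
    for (it in 1:100) {
      dup <- duplicated(substr(seqs, 1L, 18L))
      if (!any(dup)) break
      seqs[dup] <- .rand_seq(sum(dup), sample(lengths, sum(dup), TRUE))
    }
    data.frame(id = sprintf("mir-%03d", seq_len(n)), sequence = seqs,
               arm = "guide", stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic transcriptome with 3' UTR annotations
#'
#' @param n number of transcripts.
#' @param seed integer RNG seed.
#' @param len_range transcript length range (default 800-1600 nt).
#' @param utr_frac fraction of the transcript forming the 3' UTR.
#' @return data.frame with `id`, `gene`, `sequence`, `cds_end` (0-based
#'   offset where the 3' UTR begins).
#' @export
gen_transcriptome <- function(n, seed, len_range = c(800L, 1600L),
                              utr_frac = 0.4) {
  with_seed(seed, {
    lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
    data.frame(id = sprintf("tx-%03d", seq_len(n)),
               gene = sprintf("gene-%03d", seq_len(n)),
               sequence = .rand_seq(n, lens),
               cds_end = as.integer(round(lens * (1 - utr_frac))),
               stringsAsFactors = FALSE)
  })
}

# Build the target-site sequence (5'->3') implementing a pairing spec.
# The site runs antiparallel to the miRNA: its 5' part pairs the miRNA
# 3' region, its 3' part pairs the seed; an A sits opposite position 1.
.build_site <- function(mirna_seq, spec) {
  L <- nchar(mirna_seq)
  mb <- strsplit(mirna_seq, "", fixed = TRUE)[[1]]
  mode <- spec$three_prime_mode
  tp <- switch(mode,
    full_window = c(L - 7L, L),
    nine_run = c(L - 9L, L - 1L),
    seven_run = c(L - 7L, L - 1L),
    five_run = c(L - 7L, L - 3L),
    seed_only = NULL,
    perfect = NULL,
    stop("unknown three_prime_mode: ", mode)
  )
  loop_mirna <- if (identical(spec$loop_side, "mirna")) spec$loop_len else 0L
  s_end <- if (identical(mode, "perfect")) L
           else if (identical(mode, "seed_only")) 8L
           else tp[1] - loop_mirna - 1L
  if (s_end < 8L)
    stop("unsatisfiable pairing spec: seed helix would end at position ",
         s_end, " (< 8) for a ", L, "-nt miRNA")

  # per-miRNA-position target base, WC by default
  opp <- .COMP[mb]
  if (isTRUE(spec$all_gu))                      # wobble wherever possible
    opp[mb %in% c("G", "U")] <- c(G = "U", U = "G")[mb[mb %in% c("G", "U")]]
  if (!is.null(spec$n_gu) && spec$n_gu > 0L) {  # wobble inside the seed
    cand <- which(mb %in% c("G", "U"))
    cand <- cand[cand >= 3L & cand <= 7L]
    for (p in head(cand, spec$n_gu))
      opp[p] <- c(G = "U", U = "G")[mb[p]]
  }
  if (isTRUE(spec$seed_mismatch)) opp[5L] <- mb[5L]   # X-X cannot pair

  block <- function(a, b) paste(rev(opp[a:b]), collapse = "")
  loop_ins <- if (identical(spec$loop_side, "target") && !is.null(tp)) {
    # insert bases that cannot pair the helix-adjacent miRNA bases
    facing <- mb[c(s_end, min(tp[1], L))]
    pick <- if (any(facing %in% c("U", "G"))) "C" else "A"
    strrep(pick, spec$loop_len)
  } else ""

  if (identical(mode, "perfect") || identical(mode, "seed_only"))
    paste0(block(2L, s_end), "A")
  else
    paste0(block(tp[1], tp[2]), loop_ins, block(2L, s_end), "A")
}

# expected classification flags per failure mode
.expect_flags <- function(failure_mode) {
  switch(failure_mode,
    none = ,
    rpm = ,
    fold = list(candidate = TRUE),
    seed = list(candidate = FALSE, flag = "seed_ok"),
    three_prime = list(candidate = FALSE, flag = "three_prime_ok"),
    central = list(candidate = FALSE, flag = "central_ok"),
    energy = list(candidate = FALSE, flag = "energy_ok",
                  others_ok = TRUE),
    stop("unknown failure mode: ", failure_mode)
  )
}

#' Plant a pairing site for one miRNA into a transcript 3' UTR
#'
#' Writes the site implied by the pairing spec into the UTR (in place,
#' replacing existing bases) together with guarded flanks, then verifies
#' at generation time, for every fragment-start offset the read simulator
#' can produce, that folding + classification of the planted window
#' returns the expected outcome: structural candidates must satisfy all
#' four criteria with an energy margin (`dg <= dg_max - 2`), decoys must
#' fail exactly their designated criterion.  The local flanks are
#' re-drawn (up to `max_tries`) when chance complementarity breaks the
#' construction; an error lists the failed criterion otherwise.
#'
#' @param transcript one-row data.frame (`id`, `sequence`, `cds_end`).
#' @param mirna one-row data.frame (`id`, `sequence`).
#' @param spec list: `three_prime_mode` (`"full_window"`, `"nine_run"`,
#'   `"seven_run"`, `"five_run"`, `"seed_only"`, `"perfect"`),
#'   `loop_len`, `loop_side` (`"mirna"`/`"target"`), optional `n_gu`,
#'   `seed_mismatch`, `all_gu`, `site_offset` (into the UTR),
#'   `failure_mode` (`"none"` for true triggers).
#' @param config a [screen_config()].
#' @param jitter_max fragment 5'-start scatter to guard (default 3 nt).
#' @param max_tries flank re-draws before giving up.
#' @return list: `transcript` (modified row), `site_start`, `site_end`
#'   (0-based half-open), `call` (the [classify_tdmd()] row of the
#'   widest window), `site_seq`.
#' @export
plant_trigger <- function(transcript, mirna, spec,
                          config = screen_config(), jitter_max = 3L,
                          max_tries = 50L) {
  failure_mode <- spec$failure_mode %||% "none"
  expect <- .expect_flags(failure_mode)
  site <- .build_site(mirna$sequence, spec)
  slen <- nchar(site)
  offset <- spec$site_offset %||% 50L
  start0 <- transcript$cds_end + offset          # 0-based site start
  tlen <- nchar(transcript$sequence)
  frag_max <- 30L                                # widest simulated fragment
  if (start0 + max(slen, frag_max) + config$extension > tlen)
    stop("site does not fit in the 3' UTR of ", transcript$id)

  flank <- 10L
  guard_lo <- max(0L, start0 - flank)
  guard_hi <- min(tlen, start0 + slen + flank)
  mL <- substr(mirna$sequence, nchar(mirna$sequence),
               nchar(mirna$sequence))
  for (try in seq_len(max_tries)) {
    seq <- transcript$sequence
    if (try > 1L) {    # re-draw the guarded flanks
      substr(seq, guard_lo + 1L, start0) <-
        .rand_seq(1L, start0 - guard_lo)
      substr(seq, start0 + slen + 1L, guard_hi) <-
        .rand_seq(1L, guard_hi - start0 - slen)
    }
    # the 4 nt immediately 5' of the site face the miRNA 3' terminus
    # when the 3' helix stops short of position L; make them unpairable
    # with it so decoy 3'-criteria cannot be rescued by flank pairing
    if (!spec$three_prime_mode %in% c("full_window", "perfect") &&
        start0 >= 4L)
      substr(seq, start0 - 3L, start0) <- strrep(mL, 4L)
    substr(seq, start0 + 1L, start0 + slen) <- site

    ok <- TRUE
    call <- NULL
    for (j in 0:jitter_max) {
      w_start <- max(0L, start0 - j)
      w_end <- min(tlen, start0 + max(slen, frag_max) + config$extension)
      window <- substr(seq, w_start + 1L, w_end)
      duplex <- fold_duplex(mirna$sequence, window, config$model)
      call <- classify_tdmd(duplex, config)
      ok_j <- if (isTRUE(expect$candidate)) {
        call$is_candidate && call$dg <= config$dg_max - 2
      } else if (isTRUE(expect$others_ok)) {
        !call[[expect$flag]] && call$seed_ok && call$three_prime_ok &&
          call$central_ok
      } else {
        !call[[expect$flag]]
      }
      if (!ok_j) { ok <- FALSE; break }
    }
    if (ok) {
      transcript$sequence <- seq
      return(list(transcript = transcript, site_start = start0,
                  site_end = start0 + slen, call = call, site_seq = site))
    }
  }
  stop("could not plant site for ", mirna$id, " on ", transcript$id,
       ": expected ",
       if (isTRUE(expect$candidate)) "candidate with energy margin"
       else paste0("failure of ", expect$flag),
       " not realized after ", max_tries, " flank re-draws")
}

# the default study-shaped scenario: 5 true triggers + 10 decoys
.default_site_plan <- function() {
  rbind(
    data.frame(role = "trigger", failure_mode = "none",
               three_prime_mode = c("full_window", "full_window",
                                    "full_window", "nine_run",
                                    "full_window"),
               loop_len = c(2L, 4L, 6L, 1L, 3L),
               loop_side = c("mirna", "mirna", "mirna", "mirna", "target"),
               n_gu = c(0L, 1L, 0L, 0L, 2L),
               seed_mismatch = FALSE, all_gu = FALSE,
               control_mean = 15, enrichment = 8,
               min_mirna_len = c(21L, 21L, 22L, 21L, 21L),
               stringsAsFactors = FALSE),
    data.frame(role = "decoy",
               failure_mode = c("seed", "three_prime", "three_prime",
                                "three_prime", "central", "central",
                                "central", "energy", "rpm", "fold"),
               three_prime_mode = c("full_window", "seed_only",
                                    "seven_run", "five_run", "perfect",
                                    "full_window", "full_window",
                                    "full_window", "full_window",
                                    "full_window"),
               loop_len = c(2L, 0L, 2L, 2L, 0L, 7L, 8L, 2L, 3L, 3L),
               loop_side = c("mirna", "mirna", "mirna", "mirna", "mirna",
                             "mirna", "target", "mirna", "mirna",
                             "mirna"),
               n_gu = 0L, seed_mismatch = c(TRUE, rep(FALSE, 9L)),
               all_gu = c(rep(FALSE, 7L), TRUE, FALSE, FALSE),
               control_mean = c(rep(15, 8L), 0.5, 60),
               enrichment = c(rep(8, 8L), 8, 1),
               min_mirna_len = c(rep(21L, 5L), 23L, rep(21L, 4L)),
               stringsAsFactors = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete AGO-CLASH screening experiment
#'
#' Builds a synthetic miRNA set and transcriptome, plants 5 true TDMD
#' trigger sites and 10 single-criterion decoys into distinct 3' UTRs
#' (each verified at generation time), and simulates 3 control + 3
#' knockout chimeric-read libraries: each molecule is
#' 4-nt UMI + (miRNA + target fragment, order Bernoulli 0.5) + 4-nt UMI
#' + 3' adapter, with negative-binomial per-site molecule counts,
#' knockout enrichment of true-trigger (and abundance-decoy) means, PCR
#' duplication 1 + Poisson(0.5), and non-hybrid background (miRNA-only
#' and fragment-only reads, plus unmappable filler).  Bit-reproducible
#' from the seed.
#'
#' @param seed integer RNG seed.
#' @param n_mirna,n_transcripts mirnome/transcriptome sizes (50, 200).
#' @param depth raw reads per library (default 2e5).
#' @param bg_frac fraction of library molecules that are miRNA-only or
#'   fragment-only background (default 0.6).
#' @param pcr_lambda PCR duplication Poisson rate (default 0.5).
#' @param dispersion NB dispersion of per-site molecule counts (0.2).
#' @param adapter3 3' adapter sequence.
#' @param config a [screen_config()].
#' @return list: `mirnas`, `transcripts`, `sites` (the ground truth,
#'   one row per planted site with expectations), `libraries` (named
#'   list of raw read vectors), `plan` (library id, condition, depth),
#'   `params`.
#' @export
simulate_clash_experiment <- function(seed, n_mirna = 50L,
                                      n_transcripts = 200L, depth = 2e5,
                                      bg_frac = 0.6, pcr_lambda = 0.5,
                                      dispersion = 0.2,
                                      adapter3 = "AGATCGGAAGAGC",
                                      config = screen_config()) {
  mirnas <- gen_mirnome(n_mirna, seed)
  transcripts <- gen_transcriptome(n_transcripts, seed + 1L)
  plan_sites <- .default_site_plan()

  with_seed(seed + 2L, {
    # assign each planted site its own transcript and a miRNA of
    # adequate length; when a particular miRNA cannot realize the
    # pairing spec (chance self-structure of the built site), the next
    # unused candidate is tried.  The energy decoy gets a crafted
    # A/U/G-alphabet sequence whose planted pairs are weak (A-U Watson-
    # Crick and G-U/U-G wobble only), re-drawn until it verifies.
    lens <- nchar(mirnas$sequence)
    used <- integer(0)
    sites <- vector("list", nrow(plan_sites))
    for (i in seq_len(nrow(plan_sites))) {
      sp <- as.list(plan_sites[i, ])
      sp$site_offset <- 50L
      planted <- NULL
      if (sp$failure_mode == "energy") {
        mix <- which(!seq_len(nrow(mirnas)) %in% used)[1]
        for (it in 1:50) {
          weak <- paste(sample(c("A", "U", "G"), 22, replace = TRUE,
                               prob = c(0.4, 0.3, 0.3)), collapse = "")
          mirnas$sequence[mix] <- weak
          if (anyDuplicated(substr(mirnas$sequence, 1, 18))) next
          planted <- tryCatch(
            plant_trigger(transcripts[i, ], mirnas[mix, ], sp, config,
                          max_tries = 10L),
            error = function(e) NULL)
          if (!is.null(planted)) break
        }
      } else {
        for (mix in setdiff(which(lens >= sp$min_mirna_len), used)) {
          planted <- tryCatch(
            plant_trigger(transcripts[i, ], mirnas[mix, ], sp, config,
                          max_tries = 10L),
            error = function(e) NULL)
          if (!is.null(planted)) break
        }
      }
      if (is.null(planted))
        stop("could not realize pairing spec for planted site ", i,
             " (", sp$failure_mode, ") with any available miRNA")
      used <- c(used, mix)
      transcripts[i, ] <- planted$transcript
      sites[[i]] <- data.frame(
        site_id = sprintf("site-%02d", i),
        role = plan_sites$role[i],
        failure_mode = plan_sites$failure_mode[i],
        mirna_id = mirnas$id[mix],
        transcript_id = transcripts$id[i],
        site_start = planted$site_start, site_end = planted$site_end,
        control_mean = plan_sites$control_mean[i],
        enrichment = plan_sites$enrichment[i],
        expect_candidate = plan_sites$failure_mode[i] %in%
          c("none", "rpm", "fold"),
        expect_high_confidence = plan_sites$failure_mode[i] == "none",
        stringsAsFactors = FALSE
      )
    }
    sites <- do.call(rbind, sites)
  })

  plan <- data.frame(
    library_id = c(paste0("ctrl_", 1:3), paste0("ko_", 1:3)),
    condition = rep(c("control", "ko"), each = 3L),
    depth = depth, stringsAsFactors = FALSE
  )
  libraries <- list()
  for (i in seq_len(nrow(plan))) {
    libraries[[plan$library_id[i]]] <- with_seed(
      seed + 10L + i,
      sim_clash_library(mirnas, transcripts, sites, plan$condition[i],
                        depth, adapter3, bg_frac, pcr_lambda, dispersion)
    )
  }
  list(mirnas = mirnas, transcripts = transcripts, sites = sites,
       libraries = libraries, plan = plan,
       params = list(seed = seed, depth = depth, bg_frac = bg_frac,
                     pcr_lambda = pcr_lambda, dispersion = dispersion,
                     adapter3 = adapter3))
}

#' Simulate one CLASH library (uses the current RNG state)
#'
#' @param mirnas,transcripts,sites as in [simulate_clash_experiment()].
#' @param condition `"control"` or `"ko"`.
#' @param depth target raw read count.
#' @param adapter3 3' adapter appended to every read.
#' @param bg_frac,pcr_lambda,dispersion see
#'   [simulate_clash_experiment()].
#' @param frag_len fragment length range (default 22-30 nt).
#' @param jitter_max fragment 5'-start scatter (default 3 nt).
#' @return character vector of raw reads (shuffled).
#' @export
sim_clash_library <- function(mirnas, transcripts, sites, condition,
                              depth, adapter3 = "AGATCGGAAGAGC",
                              bg_frac = 0.6, pcr_lambda = 0.5,
                              dispersion = 0.2, frag_len = c(22L, 30L),
                              jitter_max = 3L) {
  mol_total <- round(depth / (1 + pcr_lambda))
  tseq <- setNames(transcripts$sequence, transcripts$id)
  mseq <- setNames(mirnas$sequence, mirnas$id)

  # planted hybrid molecules
  mu <- sites$control_mean * depth / 2e5
  if (condition == "ko") mu <- mu * sites$enrichment
  nmol <- rnbinom(nrow(sites), mu = mu, size = 1 / dispersion)
  ix <- rep(seq_len(nrow(sites)), nmol)
  n_hyb <- length(ix)
  inserts <- character(0)
  if (n_hyb) {
    jit <- sample(0:jitter_max, n_hyb, replace = TRUE)
    flen <- sample(frag_len[1]:frag_len[2], n_hyb, replace = TRUE)
    fstart <- pmax(0L, sites$site_start[ix] - jit)
    frag <- substr(tseq[sites$transcript_id[ix]], fstart + 1L,
                   fstart + flen)
    m <- mseq[sites$mirna_id[ix]]
    first <- runif(n_hyb) < 0.5
    inserts <- ifelse(first, paste0(m, frag), paste0(frag, m))
  }

  # background: miRNA-only + fragment-only (bg_frac of molecules, split
  # evenly) and unmappable filler to the depth target
  n_bg <- round(bg_frac * mol_total)
  n_m_only <- n_bg %/% 2L
  n_f_only <- n_bg - n_m_only
  m_only <- mseq[sample.int(length(mseq), n_m_only, replace = TRUE)]
  fl <- sample(25:40, n_f_only, replace = TRUE)
  tix <- sample.int(nrow(transcripts), n_f_only, replace = TRUE)
  fst <- floor(runif(n_f_only) *
                 (nchar(transcripts$sequence[tix]) - fl - 1)) + 1L
  f_only <- substr(transcripts$sequence[tix], fst, fst + fl - 1L)
  n_junk <- max(0L, mol_total - n_hyb - n_bg)
  junk <- .rand_seq(n_junk, sample(30:45, n_junk, replace = TRUE))

  all_inserts <- c(inserts, unname(m_only), f_only, junk)
  n <- length(all_inserts)
  reads <- paste0(.rand_seq(n, 4L), all_inserts, .rand_seq(n, 4L),
                  adapter3)
  copies <- 1L + rpois(n, pcr_lambda)
  sample(rep(reads, copies))
}

#' Simulate small-RNA sequencing libraries as raw reads
#'
#' Reads are mature miRNA sequences with 3'-end modification (extension
#' by 1-3 untemplated nt with probability `p_ext`, trimming by 1-3 nt
#' with probability `p_trim`), wrapped in 4-nt UMIs plus the 3' adapter.
#' For miRNAs under TDMD control (`trigger_mirnas`), `p_ext` drops from
#' 0.15 (control) to 0.05 in the trigger-knockout condition, and the
#' knockout multiplies their abundance by `trigger_fold`.
#'
#' @param mirnas data.frame with `id`, `sequence`.
#' @param trigger_mirnas ids of TDMD-regulated miRNAs.
#' @param condition `"control"` or `"ko"`.
#' @param depth molecules per library (default 5e4).
#' @param trigger_fold knockout abundance multiplier (default 2).
#' @param p_ext_control,p_ext_ko,p_trim 3'-modification rates.
#' @param dispersion NB dispersion of molecule counts (default 0.02).
#' @param base_mean named base abundances; drawn log-normal when NULL.
#' @param adapter3 3' adapter.
#' @return character vector of raw reads.
#' @export
sim_smallrna_library <- function(mirnas, trigger_mirnas, condition,
                                 depth = 5e4, trigger_fold = 2,
                                 p_ext_control = 0.15, p_ext_ko = 0.05,
                                 p_trim = 0.05, dispersion = 0.02,
                                 base_mean = NULL,
                                 adapter3 = "AGATCGGAAGAGC") {
  n_mir <- nrow(mirnas)
  if (is.null(base_mean)) {
    w <- rlnorm(n_mir, meanlog = 0, sdlog = 1)
    base_mean <- setNames(depth * w / sum(w), mirnas$id)
  }
  is_trig <- mirnas$id %in% trigger_mirnas
  mu <- base_mean[mirnas$id] *
    ifelse(is_trig & condition == "ko", trigger_fold, 1)
  nmol <- rnbinom(n_mir, mu = mu, size = 1 / dispersion)
  ix <- rep(seq_len(n_mir), nmol)
  n <- length(ix)
  seqs <- mirnas$sequence[ix]
  p_ext <- ifelse(is_trig[ix] & condition == "ko", p_ext_ko,
                  p_ext_control)
  u <- runif(n)
  ext <- u < p_ext
  trm <- !ext & u < p_ext + p_trim
  if (any(ext)) {
    el <- sample(1:3, sum(ext), replace = TRUE)
    seqs[ext] <- paste0(seqs[ext], .rand_seq(sum(ext), el))
  }
  if (any(trm)) {
    tl <- sample(1:3, sum(trm), replace = TRUE)
    seqs[trm] <- substr(seqs[trm], 1L, nchar(seqs[trm]) - tl)
  }
  sample(paste0(.rand_seq(n, 4L), seqs, .rand_seq(n, 4L), adapter3))
}

#' Simulate a miRNA count matrix with planted knockout elevation
#'
#' Negative-binomial counts for `n_per_cond` control and knockout
#' samples; the `trigger_mirnas`' knockout means are multiplied by
#' `trigger_fold`.
#'
#' @param mirnas data.frame with `id`.
#' @param trigger_mirnas ids with planted elevation.
#' @param trigger_fold true knockout/control fold (default 2).
#' @param n_per_cond samples per condition (default 3).
#' @param base_mean named mean counts; log-normal around `mean_scale`
#'   when NULL (triggers get `mean_scale` exactly, so planted effects
#'   sit at quantifiable abundance).
#' @param mean_scale median base abundance (default 2000 counts).
#' @param dispersion NB dispersion (default 0.02).
#' @return list: `counts` (matrix), `condition_of` (named vector).
#' @export
sim_mirna_counts <- function(mirnas, trigger_mirnas, trigger_fold = 2,
                             n_per_cond = 3L, base_mean = NULL,
                             mean_scale = 2000, dispersion = 0.02) {
  n_mir <- nrow(mirnas)
  if (is.null(base_mean)) {
    base_mean <- setNames(mean_scale * rlnorm(n_mir, 0, 1), mirnas$id)
    base_mean[mirnas$id %in% trigger_mirnas] <- mean_scale
  }
  samples <- c(paste0("ctrl_", seq_len(n_per_cond)),
               paste0("ko_", seq_len(n_per_cond)))
  cond <- setNames(rep(c("control", "ko"), each = n_per_cond), samples)
  counts <- sapply(samples, function(s) {
    mu <- base_mean[mirnas$id] *
      ifelse(mirnas$id %in% trigger_mirnas & cond[s] == "ko",
             trigger_fold, 1)
    rnbinom(n_mir, mu = mu, size = 1 / dispersion)
  })
  rownames(counts) <- mirnas$id
  list(counts = counts, condition_of = cond)
}

#' Simulate an mRNA count matrix with planted target repression
#'
#' @param genes character vector of gene ids.
#' @param target_genes ids whose knockout means are multiplied by
#'   `2^(-delta)`.
#' @param delta true log2 repression shift (default 0.3).
#' @param n_per_cond samples per condition (default 3).
#' @param mean_scale median base abundance (default 500 counts).
#' @param dispersion NB dispersion (default 0.1).
#' @return list: `counts`, `condition_of`.
#' @export
sim_mrna_counts <- function(genes, target_genes, delta = 0.3,
                            n_per_cond = 3L, mean_scale = 500,
                            dispersion = 0.1) {
  base_mean <- setNames(mean_scale * rlnorm(length(genes), 0, 0.8), genes)
  samples <- c(paste0("ctrl_", seq_len(n_per_cond)),
               paste0("ko_", seq_len(n_per_cond)))
  cond <- setNames(rep(c("control", "ko"), each = n_per_cond), samples)
  counts <- sapply(samples, function(s) {
    mu <- base_mean *
      ifelse(genes %in% target_genes & cond[s] == "ko", 2^(-delta), 1)
    rnbinom(length(genes), mu = mu, size = 1 / dispersion)
  })
  rownames(counts) <- genes
  list(counts = counts, condition_of = cond)
}
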