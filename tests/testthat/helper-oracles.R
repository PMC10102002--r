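# Independent oracles and fixture builders.  These deliberately avoid the
# package's own algorithms: the duplex oracle enumerates every antiparallel
# pairing recursively (no dynamic programming), the rank-test oracle walks
# bitmask subsets, and the classification oracle re-derives the screening
# rules from the pairing vector in a second style.

# --- exhaustive duplex enumeration -----------------------------------------

.oracle_pair_weight <- function(x, y, model) {
  p <- paste0(x, y)
  if (p %in% c("AU", "UA")) return(model$stack_au)
  if (p %in% c("GC", "CG")) return(model$stack_gc)
  if (model$gu_allowed && p %in% c("GU", "UG")) return(model$stack_gu)
  NA_real_
}

# minimum-energy non-empty antiparallel pairing by brute-force recursion;
# returns dg and the pair count of the best structure (max pairs on ties)
oracle_fold <- function(mirna, target, model = energy_model()) {
  n <- nchar(mirna); m <- nchar(target)
  ab <- strsplit(mirna, "")[[1]]; bb <- strsplit(target, "")[[1]]
  pw <- matrix(NA_real_, n, m)
  for (i in seq_len(n))
    for (j in seq_len(m))
      pw[i, j] <- .oracle_pair_weight(ab[i], bb[j], model)
  best_e <- Inf; best_p <- 0L
  consider <- function(e, np) {
    if (e < best_e - 1e-9) { best_e <<- e; best_p <<- np }
    else if (abs(e - best_e) < 1e-9 && np > best_p) best_p <<- np
  }
  rec <- function(i, j, e, np) {
    consider(e, np)
    if (i >= n || j <= 1L) return()
    for (i2 in (i + 1L):min(n, i + 1L + model$max_loop)) {
      l1 <- i2 - i - 1L
      for (j2 in max(1L, j - 1L - model$max_loop):(j - 1L)) {
        if (is.na(pw[i2, j2])) next
        l2 <- j - j2 - 1L
        tr <- if (l1 == 0L && l2 == 0L) -(pw[i, j] + pw[i2, j2]) / 2
        else if (l1 == 0L || l2 == 0L)
          model$bulge_open + model$bulge_per_nt * (l1 + l2)
        else model$iloop_open + model$iloop_per_nt * (l1 + l2) +
          model$iloop_asym * abs(l1 - l2)
        rec(i2, j2, e + tr, np + 1L)
      }
    }
  }
  for (i in seq_len(n))
    for (j in seq_len(m))
      if (!is.na(pw[i, j])) rec(i, j, 0, 1L)
  if (!is.finite(best_e)) list(dg = 0, n_pairs = 0L)
  else list(dg = model$init + best_e, n_pairs = best_p)
}

# --- second-path re-evaluation of the four screening rules -----------------

# operates on the pairs table only; written against the rules as stated,
# not by calling pairing_profile()
oracle_classify <- function(duplex, config = screen_config()) {
  L <- duplex$mirna_length
  pr <- duplex$pairs[order(duplex$pairs$mirna_pos), , drop = FALSE]
  paired <- rep(FALSE, L); paired[pr$mirna_pos] <- TRUE
  seed_ok <- all(paired[config$seed_span[1]:config$seed_span[2]])

  lo <- L - config$last_window + 1L
  runs <- rle(paired)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  tp <- all(paired[lo:L]) ||
    any(runs$values & runs$lengths >= config$long_run & ends >= lo)

  # stacked runs = consecutive miRNA positions with step -1 on the target
  stack_id <- cumsum(c(1L, diff(pr$mirna_pos) != 1L |
                           diff(pr$target_pos) != -1L))
  hf <- vapply(split(seq_len(nrow(pr)), stack_id), function(ix)
    c(pr$mirna_pos[ix[1]], pr$mirna_pos[ix[length(ix)]],
      pr$target_pos[ix[1]], pr$target_pos[ix[length(ix)]]),
    numeric(4))
  loop <- Inf
  if (nrow(pr)) {
    sh <- which(hf[1, ] <= config$seed_span[2] &
                hf[2, ] >= config$seed_span[1])
    if (length(sh)) {
      s <- sh[length(sh)]
      nx <- which(hf[1, ] > hf[2, s])
      if (length(nx))
        loop <- max(hf[1, nx[1]] - hf[2, s] - 1,
                    hf[4, s] - hf[3, nx[1]] - 1)
      else if (hf[2, s] >= lo) loop <- 0
    }
  }
  central_ok <- is.finite(loop) && loop >= config$loop_min &&
    loop <= config$loop_max
  energy_ok <- duplex$dg <= config$dg_max
  list(seed_ok = seed_ok, three_prime_ok = tp, central_ok = central_ok,
       energy_ok = energy_ok,
       is_candidate = seed_ok && tp && central_ok && energy_ok)
}

# --- exact Mann-Whitney by bitmask subset walk -----------------------------

oracle_mw_exact <- function(x, y) {
  v <- c(x, y); n1 <- length(x); n <- length(v)
  r <- rank(v)
  u_of <- function(idx) sum(r[idx]) - length(idx) * (length(idx) + 1) / 2
  U_obs <- u_of(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  devs <- numeric(0)
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) != n1) next
    devs <- c(devs, abs(u_of(idx) - mu))
  }
  list(U = U_obs, p_value = mean(devs >= abs(U_obs - mu) - 1e-9))
}

# --- fixture builders ------------------------------------------------------

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
          collapse = ""), character(1))
}

# a synthetic duplex_structure from an explicit pairs table (for testing
# the profile/criteria layer without folding)
make_structure <- function(mirna_pos, target_pos, L, dg = -20,
                           pair_type = "WC") {
  list(pairs = data.frame(mirna_pos = mirna_pos, target_pos = target_pos,
                          pair_type = pair_type,
                          stringsAsFactors = FALSE),
       paired = {
         p <- rep(FALSE, L); p[mirna_pos] <- TRUE; p
       },
       dg = dg, mirna_length = L, target_length = max(target_pos) + 5L)
}

# random valid hyb-dialect records (0-based half-open internally)
random_hyb_records <- function(n) {
  data.frame(
    read_id = sprintf("read_%d", seq_len(n)),
    read_sequence = random_rna(n, 50),
    dg = round(-runif(n, 0, 30), 1),
    frag1_gene_id = sprintf("mir-%03d", sample(99, n, TRUE)),
    frag1_read_start = 0L, frag1_read_end = 22L,
    frag1_gene_start = 0L, frag1_gene_end = 22L,
    frag1_score = sample(10:50, n, TRUE),
    frag2_gene_id = sprintf("tx-%03d", sample(99, n, TRUE)),
    frag2_read_start = 22L, frag2_read_end = 50L,
    frag2_gene_start = sample(100:500, n, TRUE),
    frag2_gene_end = integer(n),
    frag2_score = sample(10:50, n, TRUE),
    stringsAsFactors = FALSE
  ) -> df
  df$frag2_gene_end <- df$frag2_gene_start + 28L
  df
}
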