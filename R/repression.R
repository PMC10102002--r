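#' Reverse complement of an RNA sequence
#' @param seq character vector of RNA sequences (A/C/G/U).
#' @return reverse complements, 5'->3'.
#' @export
reverse_complement <- function(seq) {
  comp <- chartr("ACGU", "UGCA", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Predict canonical seed-match targets in 3' UTRs
#'
#' A transcript is a predicted target iff its 3' UTR contains at least
#' one canonical site against the miRNA: 8mer (Watson-Crick match to
#' miRNA positions 2-8 plus an A opposite position 1), 7mer-m8 (match to
#' 2-8), or 7mer-A1 (match to 2-7 plus the A).  G-U pairs are not
#' admitted in site matching; sites in the CDS do not count.  The best
#' site class per transcript is reported (8mer > 7mer-m8 > 7mer-A1).
#'
#' @param mirna mature miRNA sequence (or one-row data.frame with
#'   `sequence`).
#' @param transcripts data.frame with `id`, `sequence`, and `cds_end`
#'   (0-based offset where the 3' UTR begins; `NA` rows are skipped with
#'   a warning).
#' @return data.frame with `transcript_id`, `site_class`, `n_sites`.
#' @export
predict_seed_targets <- function(mirna, transcripts) {
  if (is.data.frame(mirna)) mirna <- mirna$sequence[1]
  no_utr <- is.na(transcripts$cds_end)
  if (any(no_utr)) {
    warning("skipping ", sum(no_utr), " transcript(s) without UTR annotation")
    transcripts <- transcripts[!no_utr, , drop = FALSE]
  }
  seed_m8 <- reverse_complement(substr(mirna, 2L, 8L))  # matches 2-8
  seed_m7 <- reverse_complement(substr(mirna, 2L, 7L))  # matches 2-7
  motif_8mer <- paste0(seed_m8, "A")
  motif_7m8 <- seed_m8
  motif_7a1 <- paste0(seed_m7, "A")
  utr <- substr(transcripts$sequence, transcripts$cds_end + 1L,
                nchar(transcripts$sequence))
  count_hits <- function(motif)
    vapply(gregexpr(motif, utr, fixed = TRUE),
           function(m) sum(m > 0L), integer(1))
  n8 <- count_hits(motif_8mer)
  n7m8 <- count_hits(motif_7m8) - n8       # 8mer sites also match 7mer-m8
  n7a1 <- count_hits(motif_7a1) - n8       # and 7mer-A1
  cls <- ifelse(n8 > 0L, "8mer",
                ifelse(n7m8 > 0L, "7mer-m8",
                       ifelse(n7a1 > 0L, "7mer-A1", NA_character_)))
  keep <- !is.na(cls)
  data.frame(transcript_id = transcripts$id[keep],
             site_class = cls[keep],
             n_sites = (n8 + n7m8 + n7a1)[keep],
             stringsAsFactors = FALSE)
}

#' Assemble the five target sets for repression analysis
#'
#' @param predicted gene ids of all predicted targets.
#' @param conserved gene ids of the conserved predicted subset (supplied
#'   externally; intersected with `predicted`).
#' @param clash gene ids of CLASH-identified targets.
#' @param universe all gene ids under consideration.
#' @return list of class `target_sets`: `all_predicted`,
#'   `conserved_predicted`, `clash_targets`, `overlap`
#'   (CLASH intersect predicted), `non_targets` (universe members in
#'   none of the others).
#' @export
build_target_sets <- function(predicted, conserved, clash, universe) {
  predicted <- intersect(predicted, universe)
  clash <- intersect(clash, universe)
  sets <- list(
    all_predicted = predicted,
    conserved_predicted = intersect(conserved, predicted),
    clash_targets = clash,
    overlap = intersect(clash, predicted),
    non_targets = setdiff(universe, union(predicted, clash))
  )
  structure(sets, class = "target_sets")
}

#' Cumulative fold-change distributions per target set
#'
#' Empirical CDFs of log2 fold changes over each set's kept genes
#' (baseMean-filtered upstream in [differential()]).
#'
#' @param diff_results data.frame from [differential()] (columns `gene`,
#'   `log2fc`, `kept`).
#' @param target_sets a [build_target_sets()] list.
#' @param min_n sets with fewer kept genes are flagged `low_n` (default 5).
#' @return data.frame, one row per set: `set`, `n`, `median_log2fc`,
#'   `low_n`; attribute `values` holds the per-set log2fc vectors (for
#'   plotting/tests) and attribute `ecdf` the CDF functions.
#' @export
cumulative_fold_change <- function(diff_results, target_sets, min_n = 5L) {
  kept <- diff_results[diff_results$kept, , drop = FALSE]
  vals <- lapply(target_sets, function(ids)
    kept$log2fc[kept$gene %in% ids])
  out <- data.frame(
    set = names(target_sets),
    n = vapply(vals, length, integer(1)),
    median_log2fc = vapply(vals, function(v)
      if (length(v)) median(v) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE
  )
  out$low_n <- out$n < min_n
  attr(out, "values") <- vals
  attr(out, "ecdf") <- lapply(vals, function(v)
    if (length(v)) ecdf(v) else NULL)
  out
}

#' Plot cumulative fold-change curves
#' @param cfc result of [cumulative_fold_change()].
#' @param main plot title.
#' @export
plot_cfc <- function(cfc, main = "Cumulative fold-change distributions") {
  vals <- attr(cfc, "values")
  vals <- vals[vapply(vals, length, integer(1)) > 0]
  xs <- range(unlist(vals))
  cols <- c(all_predicted = "darkorange", conserved_predicted = "red3",
            clash_targets = "dodgerblue3", overlap = "forestgreen",
            non_targets = "black")
  graphics::plot(NULL, xlim = xs, ylim = c(0, 1),
                 xlab = expression(log[2] ~ "fold change"),
                 ylab = "cumulative fraction", main = main)
  for (nm in names(vals)) {
    v <- sort(vals[[nm]])
    graphics::lines(v, seq_along(v) / length(v), col = cols[[nm]], lwd = 2)
  }
  graphics::legend("bottomright", legend = names(vals),
                   col = cols[names(vals)], lwd = 2, bty = "n", cex = 0.8)
  invisible(cfc)
}

#' Two-sided Mann-Whitney U test
#'
#' U is the rank-sum statistic of `x` versus `y` (midranks under ties).
#' The two-sided P value comes from exact enumeration of the permutation
#' null (all reassignments of the observed values to the two groups)
#' when the smaller sample has at most `exact_max_n` observations and
#' the enumeration is tractable (`choose(n1 + n2, min(n1, n2)) <=
#' enum_cap`); otherwise from the normal approximation with continuity
#' and midrank tie corrections.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_max_n largest min-sample size for the exact path (8).
#' @param enum_cap largest enumeration size attempted (5e5 subsets).
#' @return list with `U`, `p_value`, `method` (`"exact"`/`"normal"`).
#' @export
mann_whitney_two_sided <- function(x, y, exact_max_n = 8L, enum_cap = 5e5) {
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  exact_ok <- min(n1, n2) <= exact_max_n &&
    choose(n, min(n1, n2)) <= enum_cap
  if (exact_ok) {
    k <- min(n1, n2)
    idx <- combn(n, k)
    # U of the smaller group; symmetric around k*(n-k)/2
    Us <- colSums(matrix(r[idx], nrow = k)) - k * (k + 1) / 2
    mu_k <- k * (n - k) / 2
    U_ref <- if (n1 <= n2) U_obs else n1 * n2 - U_obs  # U of smaller group
    p <- mean(abs(Us - mu_k) >= abs(U_ref - mu_k) - 1e-9)
    return(list(U = U_obs, p_value = p, method = "exact"))
  }

  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0)
    return(list(U = U_obs, p_value = 1, method = "normal"))
  z <- (U_obs - mu - sign(U_obs - mu) * 0.5) / sqrt(sig2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(U = U_obs, p_value = p, method = "normal")
}

#' Organ-normalized correlation between miRNAs and trigger transcripts
#'
#' For each entity (miRNA or transcript), the normalized abundance is
#' its whole-body value divided by its mean across organ columns.
#' Pearson correlation is pooled over the supplied miRNA/trigger pairs,
#' with a two-tailed P value from the t transform on n - 2 degrees of
#' freedom (withheld when fewer than 3 pairs survive).
#'
#' @param mirna_matrix,trigger_matrix numeric matrices, entities x
#'   organs, containing a whole-body column.
#' @param pairs data.frame with `mirna_id`, `transcript_id` (rownames of
#'   the two matrices).
#' @param whole_body name of the whole-body column (default
#'   `"whole_body"`).
#' @param log2 correlate log2-transformed normalized abundances instead
#'   of linear ones (default FALSE).
#' @return list: `pairs` (per-pair normalized values), `r`, `p_value`,
#'   `n`.
#' @export
organ_normalized_correlation <- function(mirna_matrix, trigger_matrix, pairs,
                                         whole_body = "whole_body",
                                         log2 = FALSE) {
  norm_one <- function(mat, id) {
    organs <- setdiff(colnames(mat), whole_body)
    if (length(organs) < 2L) stop("need >= 2 organ columns")
    om <- mean(mat[id, organs])
    if (om == 0) return(NA_real_)
    mat[id, whole_body] / om
  }
  mv <- vapply(pairs$mirna_id, norm_one, numeric(1), mat = mirna_matrix)
  tv <- vapply(pairs$transcript_id, norm_one, numeric(1),
               mat = trigger_matrix)
  keep <- is.finite(mv) & is.finite(tv)
  if (any(!keep))
    warning("skipping ", sum(!keep), " pair(s) with zero organ mean")
  mv <- mv[keep]; tv <- tv[keep]
  if (log2) { mv <- base::log2(mv); tv <- base::log2(tv) }
  if (stats::sd(mv) == 0 || stats::sd(tv) == 0)
    stop("zero variance: correlation undefined")
  n <- length(mv)
  r <- stats::cor(mv, tv)
  p <- NA_real_
  if (n >= 3L) {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(pairs = data.frame(mirna_id = pairs$mirna_id[keep],
                          transcript_id = pairs$transcript_id[keep],
                          mirna_norm = mv, trigger_norm = tv,
                          stringsAsFactors = FALSE),
       r = r, p_value = p, n = n)
}
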