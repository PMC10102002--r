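#' Count small-RNA reads per miRNA by 18-nt prefix identity
#'
#' A clean read is assigned to a miRNA iff its first `prefix_len` (18)
#' nucleotides equal the first 18 nucleotides of the mature sequence;
#' 3' tails and length variants do not affect assignment.  Reads whose
#' prefix matches several miRNAs are counted once for each and flagged
#' in the report.  Each collapsed molecule counts 1 (PCR copies were
#' already removed).  miRNAs shorter than the prefix are excluded with a
#' warning.
#'
#' @param clean_reads `data.table` with an `insert` column (length >= 18).
#' @param mirna_set data.frame with `id`, `sequence`.
#' @param prefix_len matching prefix length (default 18).
#' @return named integer vector of counts (one per miRNA, zero included);
#'   attribute `report` carries `n_assigned`, `n_ambiguous`,
#'   `n_unassigned`.
#' @export
count_mirna_reads <- function(clean_reads, mirna_set, prefix_len = 18L) {
  short <- nchar(mirna_set$sequence) < prefix_len
  if (any(short)) {
    warning("excluding ", sum(short), " miRNA(s) shorter than ", prefix_len,
            " nt: ", paste(mirna_set$id[short], collapse = ", "))
    mirna_set <- mirna_set[!short, , drop = FALSE]
  }
  pre <- substr(mirna_set$sequence, 1L, prefix_len)
  rp <- substr(clean_reads$insert, 1L, prefix_len)
  counts <- setNames(integer(nrow(mirna_set)), mirna_set$id)
  n_matches <- integer(length(rp))
  for (i in seq_len(nrow(mirna_set))) {
    hit <- rp == pre[i]
    counts[i] <- sum(hit)
    n_matches <- n_matches + hit
  }
  attr(counts, "report") <- list(
    n_assigned = sum(n_matches > 0L),
    n_ambiguous = sum(n_matches > 1L),
    n_unassigned = sum(n_matches == 0L)
  )
  counts
}

#' Read-length distribution of one miRNA's assigned reads
#'
#' Reads are assigned by the 18-nt prefix rule; the distribution covers
#' lengths `range` (default 18-26 nt) and sums to 1 when any assigned
#' read falls in range.  Out-of-range assigned reads are excluded.
#'
#' @param clean_reads `data.table` with an `insert` column.
#' @param mirna one mature sequence (or a one-row data.frame slice).
#' @param range integer vector of lengths (default `18:26`).
#' @param prefix_len matching prefix length (default 18).
#' @return named numeric vector of fractions over `range`; attribute
#'   `n` = assigned in-range read count (all-zero vector flagged by
#'   `n = 0`).
#' @export
length_distribution <- function(clean_reads, mirna, range = 18:26,
                                prefix_len = 18L) {
  if (is.data.frame(mirna)) mirna <- mirna$sequence[1]
  pre <- substr(mirna, 1L, prefix_len)
  lens <- nchar(clean_reads$insert)
  assigned <- lens[substr(clean_reads$insert, 1L, prefix_len) == pre]
  assigned <- assigned[assigned %in% range]
  fr <- setNames(numeric(length(range)), range)
  if (length(assigned)) {
    tab <- table(factor(assigned, levels = range))
    fr[] <- as.numeric(tab) / length(assigned)
  }
  attr(fr, "n") <- length(assigned)
  fr
}

#' Reads-per-million normalization
#'
#' @param matrix counts, genes x samples; every column sum must be > 0.
#' @return numeric matrix where each column sums to 1e6.
#' @export
rpm_normalize <- function(matrix) {
  cs <- colSums(matrix)
  zero <- cs == 0
  if (any(zero))
    stop("all-zero sample column(s): ",
         paste(colnames(matrix)[zero], collapse = ", "))
  sweep(matrix, 2, cs / 1e6, "/")
}

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over genes (restricted to
#' genes whose geometric mean across samples is positive, i.e. nonzero
#' in every sample) of `count[g, s] / geomean_g`.
#'
#' @param matrix counts, genes x samples.
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(matrix) {
  logm <- log(matrix)
  use <- rowSums(!is.finite(logm)) == 0
  if (!any(use))
    stop("no gene with nonzero counts in every sample")
  geo <- exp(rowMeans(logm[use, , drop = FALSE]))
  apply(matrix[use, , drop = FALSE], 2, function(cnt) median(cnt / geo))
}

#' Size-factor-normalized counts
#' @param matrix counts, genes x samples.
#' @param factors optional precomputed [size_factors()].
#' @return numeric matrix of normalized counts.
#' @export
normalize_counts <- function(matrix, factors = size_factors(matrix)) {
  sweep(matrix, 2, factors, "/")
}

#' Effect sizes with baseMean expression filters
#'
#' baseMean is the average of size-factor-normalized counts across all
#' samples; log2 fold change is computed on per-condition means of
#' normalized counts with a 0.5 pseudocount.  Genes with baseMean below
#' 200 (miRNA) or 100 (mRNA) are flagged filtered-out (`kept = FALSE`);
#' the boundary value is kept.
#'
#' @param matrix counts, genes x samples.
#' @param condition_of named character vector: sample -> condition.
#' @param kind `"mirna"` (filter 200) or `"mrna"` (filter 100).
#' @param control_condition,ko_condition condition labels.
#' @return data.frame per gene: `baseMean`, `log2fc` (KO vs control),
#'   `kept`.
#' @export
differential <- function(matrix, condition_of, kind = c("mirna", "mrna"),
                         control_condition = "control",
                         ko_condition = "ko") {
  kind <- match.arg(kind)
  stopifnot(all(colnames(matrix) %in% names(condition_of)))
  cond <- condition_of[colnames(matrix)]
  if (length(unique(cond)) < 2L)
    stop("both conditions must be present")
  if (sum(cond == control_condition) < 2L || sum(cond == ko_condition) < 2L)
    stop("need >= 2 samples per condition")
  norm <- normalize_counts(matrix)
  base_mean <- rowMeans(norm)
  m_ctrl <- rowMeans(norm[, cond == control_condition, drop = FALSE])
  m_ko <- rowMeans(norm[, cond == ko_condition, drop = FALSE])
  threshold <- if (kind == "mirna") 200 else 100
  data.frame(
    gene = rownames(matrix),
    baseMean = base_mean,
    log2fc = log2((m_ko + 0.5) / (m_ctrl + 0.5)),
    kept = base_mean >= threshold,
    stringsAsFactors = FALSE
  )
}
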