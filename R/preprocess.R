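#' Trim a 3' sequencing adapter from read ends
#'
#' Removes the longest read suffix that matches a prefix of `adapter3`
#' exactly, requiring at least `min_overlap` nucleotides of overlap.
#' Internal adapter occurrences are not searched; reads without a
#' qualifying suffix are returned unchanged.
#'
#' @param read_sequence character vector of read sequences.
#' @param adapter3 the 3' adapter sequence (non-empty).
#' @param min_overlap minimum exact suffix/prefix overlap (default 5).
#' @return character vector of trimmed sequences.
#' @export
trim_adapter <- function(read_sequence, adapter3, min_overlap = 5L) {
  stopifnot(nchar(adapter3) > 0)
  n <- nchar(read_sequence)
  trimmed <- read_sequence
  best <- integer(length(read_sequence))
  todo <- seq_along(read_sequence)
  for (ov in seq(nchar(adapter3), min_overlap)) {  # longest overlap first
    if (!length(todo)) break
    apre <- substr(adapter3, 1L, ov)
    hit <- n[todo] >= ov &
      substr(read_sequence[todo], n[todo] - ov + 1L, n[todo]) == apre
    best[todo[hit]] <- ov
    todo <- todo[!hit]
  }
  has <- best > 0L
  trimmed[has] <- substr(read_sequence[has], 1L, n[has] - best[has])
  trimmed
}

#' Collapse PCR duplicates on the 4-nt random ends
#'
#' Reads identical over the full (5'-UMI, insert, 3'-UMI) triple collapse
#' to one molecule; the UMIs (the `umi_len` random nucleotides at each
#' end) are stripped from the insert.  Reads shorter than
#' `2 * umi_len + 1` cannot contain both UMIs plus an insert and are
#' dropped (counted in the attached report).  Output order is
#' deterministic: lexicographic by insert, then 5' UMI, then 3' UMI.
#'
#' @param reads character vector of (adapter-trimmed) read sequences.
#' @param umi_len UMI length at each end (default 4).
#' @return `data.table` with columns `insert`, `umi5`, `umi3`, `copies`;
#'   attribute `report` holds `n_in`, `n_dropped_short`, `n_molecules`.
#' @export
collapse_umi_duplicates <- function(reads, umi_len = 4L) {
  n_in <- length(reads)
  len <- nchar(reads)
  keep <- len >= 2L * umi_len + 1L
  dropped <- sum(!keep)
  # collapse on the whole read first (one-column radix count), then
  # split UMIs on the much smaller set of unique molecules
  out <- data.table(read = reads[keep])[, .(copies = .N), by = read]
  rlen <- nchar(out$read)
  out[, `:=`(umi5 = substr(read, 1L, umi_len),
             insert = substr(read, umi_len + 1L, rlen - umi_len),
             umi3 = substr(read, rlen - umi_len + 1L, rlen))]
  out[, read := NULL]
  setorder(out, insert, umi5, umi3)
  setcolorder(out, c("insert", "umi5", "umi3", "copies"))
  setattr(out, "report",
          list(n_in = n_in, n_dropped_short = dropped, n_molecules = nrow(out)))
  out[]
}

#' Remove inserts below the minimum length
#'
#' @param clean_reads `data.table` from [collapse_umi_duplicates()].
#' @param min_length minimum insert length kept (default 18; inserts of
#'   exactly `min_length` nucleotides are retained).
#' @return filtered `data.table`; attribute `report` holds `n_in`,
#'   `n_removed_short`, `n_out`.
#' @export
filter_min_length <- function(clean_reads, min_length = 18L) {
  keep <- nchar(clean_reads$insert) >= min_length
  out <- clean_reads[keep]
  setattr(out, "report",
          list(n_in = nrow(clean_reads), n_removed_short = sum(!keep),
               n_out = nrow(out)))
  out[]
}

#' Full read cleanup: adapter trim, UMI collapse, length filter
#'
#' Fixed stage order trim -> collapse -> length-filter.
#'
#' @param reads character vector of raw read sequences.
#' @param adapter3 3' adapter sequence.
#' @param umi_len UMI length at each end (default 4).
#' @param min_length minimum insert length (default 18).
#' @param min_overlap minimum adapter overlap (default 5).
#' @return `data.table` of clean reads (`insert`, `umi5`, `umi3`,
#'   `copies`) with a consolidated `report` attribute.
#' @export
preprocess_reads <- function(reads, adapter3, umi_len = 4L,
                             min_length = 18L, min_overlap = 5L) {
  trimmed <- trim_adapter(reads, adapter3, min_overlap)
  collapsed <- collapse_umi_duplicates(trimmed, umi_len)
  rep1 <- attr(collapsed, "report")
  out <- filter_min_length(collapsed, min_length)
  rep2 <- attr(out, "report")
  setattr(out, "report", list(
    n_raw = length(reads),
    n_dropped_short = rep1$n_dropped_short,
    n_molecules = rep1$n_molecules,
    n_removed_below_min = rep2$n_removed_short,
    n_clean = rep2$n_out
  ))
  out[]
}
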