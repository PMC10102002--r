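#' Build an exact k-mer index over a transcriptome
#'
#' Every k-mer occurrence (transcript, 0-based offset) is retrievable;
#' transcripts shorter than `k` are skipped with a warning.
#'
#' @param transcripts data.frame with columns `id`, `sequence`.
#' @param k k-mer size (default 12).
#' @return list of class `kmer_index` with the keyed occurrence table and
#'   the transcript sequences.
#' @export
build_kmer_index <- function(transcripts, k = 12L) {
  k <- as.integer(k)
  lens <- nchar(transcripts$sequence)
  short <- lens < k
  if (any(short))
    warning(sum(short), " transcript(s) shorter than k = ", k, " skipped")
  keep <- which(!short)
  tabs <- lapply(keep, function(i) {
    L <- lens[i]
    data.table(kmer = substring(transcripts$sequence[i], 1:(L - k + 1L), k:L),
               transcript_id = transcripts$id[i],
               pos = 0:(L - k))      # 0-based offsets
  })
  occ <- rbindlist(tabs)
  if (!nrow(occ))
    occ <- data.table(kmer = character(0), transcript_id = character(0),
                      pos = integer(0))
  setkey(occ, kmer)
  structure(list(k = k, occurrences = occ,
                 sequences = setNames(transcripts$sequence, transcripts$id),
                 lengths = setNames(lens, transcripts$id)),
            class = "kmer_index")
}

#' Map a fragment to the transcriptome by exact match
#'
#' k-mer seed (the fragment's first k-mer) plus full-length verification.
#' All exact hits are returned; resolution of multi-transcript hits is the
#' caller's responsibility.
#'
#' @param fragment fragment sequence (>= k nt).
#' @param index a [build_kmer_index()].
#' @return data.frame with `transcript_id`, `start`, `end` (0-based
#'   half-open); zero rows when there is no exact hit.
#' @export
map_fragment <- function(fragment, index) {
  flen <- nchar(fragment)
  if (flen < index$k)
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0)))
  seed <- substr(fragment, 1L, index$k)
  cand <- index$occurrences[.(seed), nomatch = NULL]
  if (!nrow(cand))
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0)))
  ok <- substr(index$sequences[cand$transcript_id], cand$pos + 1L,
               cand$pos + flen) == fragment
  hits <- cand[ok]
  out <- data.frame(transcript_id = hits$transcript_id,
                    start = hits$pos, end = hits$pos + flen,
                    stringsAsFactors = FALSE)
  out[order(out$transcript_id, out$start), , drop = FALSE]
}

#' Extend a target hit 25 nt on its 3' end
#'
#' Compensates for nuclease trimming of the target fragment; the
#' extension is clamped at the transcript end.  Vectorized.
#'
#' @param start,end 0-based half-open hit interval(s).
#' @param transcript_length transcript length(s).
#' @param n extension length (default 25).
#' @return data.frame with extended `start`, `end`.
#' @export
extend_target_3prime <- function(start, end, transcript_length, n = 25L) {
  data.frame(start = start, end = pmin(end + n, transcript_length))
}

# longest common prefix length of a and b starting at position `from`
.lcp_from <- function(a, b, from) {
  top <- min(nchar(a), nchar(b))
  p <- from - 1L
  while (p < top && substr(a, p + 1L, p + 1L) == substr(b, p + 1L, p + 1L))
    p <- p + 1L
  p
}

#' Split one clean chimeric read into miRNA arm and target fragment
#'
#' Finds a miRNA whose first `prefix_len` (18) nucleotides match exactly
#' at the read 5' start, or whose aligned block (a prefix of the mature
#' sequence, >= 18 nt) ends at the read 3' end.  The arm may extend up to
#' the full mature length; with `tail > 0`, that many untemplated
#' nucleotides after a complete mature match are consumed and assigned to
#' neither arm nor fragment.  The longest match wins; ties break
#' lexicographically by miRNA id, then 5' placement.
#'
#' @param insert clean read sequence (>= 30 nt).
#' @param mirna_set data.frame with `id`, `sequence`.
#' @param config a [screen_config()].
#' @param tail untemplated 3'-tail length to consume (0..`tail_max`).
#' @return list (`mirna_id`, `mirna_span` 0-based half-open on the read,
#'   `fragment`, `order` = `"mirna_first"`/`"mirna_last"`) or `NULL`.
#' @export
split_chimera <- function(insert, mirna_set, config = screen_config(),
                          tail = 0L) {
  n <- nchar(insert)
  if (n < 30L) return(NULL)
  plen <- config$prefix_len
  best <- NULL
  # 5' placement
  for (i in seq_len(nrow(mirna_set))) {
    m <- mirna_set$sequence[i]
    if (substr(insert, 1L, plen) == substr(m, 1L, plen)) {
      ml <- .lcp_from(insert, m, plen)
      cons <- ml + if (ml == nchar(m)) tail else 0L
      frag <- substr(insert, cons + 1L, n)
      if (nchar(frag) >= config$min_fragment &&
          (is.null(best) || ml > best$match_len ||
           (ml == best$match_len && mirna_set$id[i] < best$mirna_id &&
            best$order != "mirna_first")))
        best <- list(mirna_id = mirna_set$id[i], match_len = ml,
                     mirna_span = c(0L, cons), fragment = frag,
                     order = "mirna_first")
    }
  }
  # 3' placement: block = prefix of the mature sequence ending at read end
  for (i in seq_len(nrow(mirna_set))) {
    m <- mirna_set$sequence[i]
    Lm <- nchar(m)
    for (p in seq(min(Lm, n - config$min_fragment), plen)) {
      blk_start <- n - tail - p + 1L
      if (blk_start < 1L) next
      if (substr(insert, blk_start, n - tail) == substr(m, 1L, p)) {
        if (p < Lm && tail > 0L) break  # tails only after a complete match
        cons <- p + tail
        frag <- substr(insert, 1L, n - cons)
        if (nchar(frag) >= config$min_fragment &&
            (is.null(best) || p > best$match_len ||
             (p == best$match_len && best$order == "mirna_last" &&
              mirna_set$id[i] < best$mirna_id)))
          best <- list(mirna_id = mirna_set$id[i], match_len = p,
                       mirna_span = c(n - cons, n), fragment = frag,
                       order = "mirna_last")
        break
      }
    }
  }
  if (is.null(best)) return(NULL)
  best[c("mirna_id", "mirna_span", "fragment", "order")]
}

# vectorized chimera splitting over many inserts; tail = 0 path.
# 5' placement is resolved first; a 3' placement only wins with a
# strictly longer match, so ties prefer the 5' arm.
.split_chimeras <- function(inserts, mirna_set, config) {
  plen <- config$prefix_len
  n <- nchar(inserts)
  res <- data.table(idx = seq_along(inserts), n = n,
                    mirna_id = NA_character_, match_len = 0L,
                    order = NA_character_, fragment = NA_character_)
  eligible <- n >= 30L
  mt <- data.table(id = mirna_set$id, seq = mirna_set$sequence,
                   len = nchar(mirna_set$sequence),
                   prefix = substr(mirna_set$sequence, 1L, plen))
  setorder(mt, id)                 # lexicographic tie-break order

  # 5' placement: hash lookup of the read's first 18 nt, then extension
  p18 <- substr(inserts, 1L, plen)
  gi <- match(p18, mt$prefix)      # first (lexicographic) owner of prefix
  cand_rows <- which(!is.na(gi) & eligible)
  for (r in sort(unique(gi[cand_rows]))) {
    members <- which(mt$prefix == mt$prefix[r])   # usually length 1
    hit <- cand_rows[gi[cand_rows] == r]
    best_ml <- integer(length(hit))
    best_m <- integer(length(hit))
    for (mix in members) {         # longest match wins, first id on ties
      full <- substr(inserts[hit], 1L, mt$len[mix]) == mt$seq[mix]
      ml <- integer(length(hit))
      ml[full] <- mt$len[mix]
      if (any(!full))
        ml[!full] <- vapply(inserts[hit[!full]], .lcp_from, integer(1),
                            b = mt$seq[mix], from = plen)
      gain <- ml > best_ml
      best_ml[gain] <- ml[gain]
      best_m[gain] <- mix
    }
    ok <- n[hit] - best_ml >= config$min_fragment &
      best_ml > res$match_len[hit]
    upd <- hit[ok]
    if (length(upd)) {
      frag_new <- substr(inserts[upd], best_ml[ok] + 1L, n[upd])
      ml_new <- best_ml[ok]
      id_new <- mt$id[best_m[ok]]
      res[upd, `:=`(mirna_id = id_new, match_len = ml_new,
                    order = "mirna_first", fragment = frag_new)]
    }
  }

  # 3' placement: mature-sequence prefix of length p >= plen ending at
  # the read 3' end.  One hash pass: the read's last plen nucleotides
  # must equal positions (p-plen+1)..p of the mature sequence for some
  # admissible p; candidates are then verified and the longest p wins.
  shifts <- list()
  for (r in seq_len(nrow(mt)))
    for (p in seq(plen, mt$len[r]))
      shifts[[length(shifts) + 1L]] <-
        data.table(blk18 = substr(mt$seq[r], p - plen + 1L, p),
                   mrow = r, p = p)
  shifts <- rbindlist(shifts)
  setorder(shifts, -p, mrow)       # longest block, then lexicographic id
  sufp <- substr(inserts, n - plen + 1L, n)
  cand3 <- which(eligible & sufp %in% shifts$blk18)
  if (length(cand3)) {
    for (p in seq(max(mt$len), plen)) {   # longest block first
      has <- which(mt$len >= p)
      blocks <- substr(mt$seq[has], 1L, p)
      live <- cand3[res$match_len[cand3] < p &
                    n[cand3] - p >= config$min_fragment]
      if (!length(live)) next
      mm <- match(substr(inserts[live], n[live] - p + 1L, n[live]),
                  blocks)                 # first = lexicographic on ties
      upd <- live[!is.na(mm)]
      if (length(upd)) {
        id_new <- mt$id[has[mm[!is.na(mm)]]]
        frag_new <- substr(inserts[upd], 1L, n[upd] - p)
        res[upd, `:=`(mirna_id = id_new, match_len = p,
                      order = "mirna_last", fragment = frag_new)]
      }
    }
  }
  res[!is.na(mirna_id)]
}

# map many fragments at once: first-kmer join + substring verification;
# returns one row per (fragment row, hit)
.map_fragments <- function(frags, index) {
  dt <- data.table(row = seq_along(frags), frag = frags,
                   flen = nchar(frags))
  dt <- dt[flen >= index$k]
  if (!nrow(dt))
    return(data.table(row = integer(0), transcript_id = character(0),
                      start = integer(0), end = integer(0)))
  dt[, kmer := substr(frag, 1L, index$k)]
  cand <- index$occurrences[dt, on = "kmer", nomatch = NULL,
                            allow.cartesian = TRUE]
  if (!nrow(cand)) return(cand[, .(row, transcript_id, start = pos, end = pos)])
  ok <- substr(index$sequences[cand$transcript_id], cand$pos + 1L,
               cand$pos + cand$flen) == cand$frag
  cand <- cand[ok]
  cand[, .(row, transcript_id, start = pos, end = pos + flen)]
}

#' Call hybrids for a set of cleaned CLASH libraries
#'
#' Splits clean reads into miRNA arm + target fragment, maps fragments to
#' the transcriptome by exact match, extends hits 25 nt on the 3' end,
#' and aggregates per-site molecule counts per library.  Fragments
#' hitting several transcripts are assigned to the transcript with the
#' highest uniquely-mapped hybrid support (ties lexicographic), flagged
#' `ambiguous`.  When a fragment fails to map and the miRNA arm matched
#' its complete mature sequence, up to `tail_max` leading (or trailing,
#' for 3'-placed miRNAs) fragment nucleotides are consumed as an
#' untemplated tail and mapping is retried.
#'
#' @param libraries named list of clean-read `data.table`s
#'   (from [preprocess_reads()]).
#' @param mirna_set data.frame with `id`, `sequence`.
#' @param transcripts data.frame with `id`, `sequence`.
#' @param config a [screen_config()].
#' @return list: `records` (`data.table` of per-library hybrid sites:
#'   `mirna_id`, `transcript_id`, `site_start`, `site_end`, `library_id`,
#'   `read_count`, `ambiguous`), `stats` (per-library read accounting),
#'   `index` (the k-mer index, reusable).
#' @export
call_hybrids <- function(libraries, mirna_set, transcripts,
                         config = screen_config()) {
  index <- build_kmer_index(transcripts, config$kmer)
  all_records <- list()
  stats <- list()
  for (lib in names(libraries)) {
    reads <- libraries[[lib]]
    splits <- .split_chimeras(reads$insert, mirna_set, config)
    hits <- .map_fragments(splits$fragment, index)
    # untemplated-tail retry for unmapped full-length arms
    unmapped <- setdiff(seq_len(nrow(splits)), unique(hits$row))
    if (length(unmapped) && config$tail_max > 0L) {
      mlen <- setNames(nchar(mirna_set$sequence), mirna_set$id)
      for (t in seq_len(config$tail_max)) {
        um <- splits[unmapped]
        full <- um$match_len == mlen[um$mirna_id]
        cand <- unmapped[full]
        if (!length(cand)) break
        fr <- splits$fragment[cand]
        fr_t <- ifelse(splits$order[cand] == "mirna_first",
                       substr(fr, t + 1L, nchar(fr)),
                       substr(fr, 1L, nchar(fr) - t))
        keep <- nchar(fr_t) >= config$min_fragment
        h2 <- .map_fragments(fr_t[keep], index)
        if (nrow(h2)) {
          h2[, row := cand[keep][row]]
          hits <- rbind(hits, h2)
          unmapped <- setdiff(unmapped, unique(h2$row))
        }
      }
    }
    if (nrow(hits)) {
      # resolve multi-transcript hits by unique-support, then lexicographic
      nh <- hits[, .N, by = row]
      uniq_rows <- nh$row[nh$N == 1L]
      support <- hits[row %in% uniq_rows, .N, by = transcript_id]
      hits <- merge(hits, support, by = "transcript_id", all.x = TRUE)
      hits[is.na(N), N := 0L]
      setorder(hits, row, -N, transcript_id)
      hits[, ambiguous := .N > 1L, by = row]
      hits <- hits[, .SD[1L], by = row]
    } else {
      hits[, ambiguous := logical(0)]
    }
    ext <- extend_target_3prime(hits$start, hits$end,
                                unname(index$lengths[hits$transcript_id]),
                                config$extension)
    rec <- data.table(mirna_id = splits$mirna_id[hits$row],
                      transcript_id = hits$transcript_id,
                      site_start = ext$start, site_end = ext$end,
                      ambiguous = hits$ambiguous)
    rec <- rec[, .(read_count = .N, ambiguous = any(ambiguous)),
               by = .(mirna_id, transcript_id, site_start, site_end)]
    rec[, library_id := lib]
    all_records[[lib]] <- rec
    stats[[lib]] <- list(n_clean = nrow(reads), n_split = nrow(splits),
                         n_hybrid = length(unique(hits$row)),
                         n_nonhybrid = nrow(reads) - length(unique(hits$row)))
  }
  list(records = rbindlist(all_records), stats = stats, index = index)
}

#' Merge hybrid sites and compute per-condition RPM and enrichment
#'
#' Records sharing (miRNA, transcript) whose site intervals lie within
#' `merge_distance` nt are merged (union interval, summed counts).
#' Per-condition RPM = 1e6 * summed site counts / total clean reads of
#' that condition's libraries (or total hybrid reads when the config's
#' `rpm_denominator` is `"hybrid"`).  Fold change =
#' `(ko_rpm + p) / (control_rpm + p)` with pseudocount `p` (0.1 RPM);
#' sites absent from control are flagged `ctrl_zero`.
#'
#' @param records hybrid-site records from [call_hybrids()].
#' @param library_condition_map named character vector: library id ->
#'   condition.
#' @param clean_totals named numeric vector: library id -> total clean
#'   reads (the RPM denominator source when `rpm_denominator = "all"`).
#' @param config a [screen_config()].
#' @param control_condition,ko_condition condition labels.
#' @return data.frame, one row per merged site: counts, RPM per
#'   condition, `fold_change`, `ctrl_zero`.
#' @export
aggregate_hybrids <- function(records, library_condition_map, clean_totals,
                              config = screen_config(),
                              control_condition = "control",
                              ko_condition = "ko") {
  libs <- unique(records$library_id)
  if (!all(libs %in% names(library_condition_map)))
    stop("library id(s) without condition mapping: ",
         paste(setdiff(libs, names(library_condition_map)), collapse = ", "))
  conds <- library_condition_map
  if (!all(conds %in% c(control_condition, ko_condition)))
    stop("conditions must be '", control_condition, "' or '",
         ko_condition, "'")
  rec <- as.data.table(records)
  setorder(rec, mirna_id, transcript_id, site_start, site_end, library_id)
  rec[, cluster := {
    cummax_end <- Reduce(max, site_end, accumulate = TRUE)
    prev_end <- c(-1e9, head(cummax_end, -1))
    cumsum(site_start > prev_end + config$merge_distance)
  }, by = .(mirna_id, transcript_id)]
  merged <- rec[, .(site_start = min(site_start), site_end = max(site_end),
                    count = sum(read_count), ambiguous = any(ambiguous)),
                by = .(mirna_id, transcript_id, cluster, library_id)]
  site <- merged[, .(site_start = min(site_start), site_end = max(site_end),
                     control_count = sum(count[conds[library_id] ==
                                                 control_condition]),
                     ko_count = sum(count[conds[library_id] == ko_condition]),
                     ambiguous = any(ambiguous)),
                 by = .(mirna_id, transcript_id, cluster)]
  site[, cluster := NULL]

  denom <- function(cond) {
    lib_ids <- names(conds)[conds == cond]
    if (config$rpm_denominator == "all") {
      if (!all(lib_ids %in% names(clean_totals)))
        stop("clean_totals missing for libraries: ",
             paste(setdiff(lib_ids, names(clean_totals)), collapse = ", "))
      sum(clean_totals[lib_ids])
    } else {
      sum(records$read_count[conds[records$library_id] == cond])
    }
  }
  d_ctrl <- denom(control_condition)
  d_ko <- denom(ko_condition)
  site[, `:=`(control_rpm = 1e6 * control_count / d_ctrl,
              ko_rpm = 1e6 * ko_count / d_ko)]
  p <- config$rpm_pseudo
  site[, `:=`(fold_change = (ko_rpm + p) / (control_rpm + p),
              ctrl_zero = control_count == 0L)]
  setorder(site, mirna_id, transcript_id, site_start)
  as.data.frame(site)
}
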