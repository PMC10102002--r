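#' Screen configuration: every numeric threshold in one place
#'
#' Defaults are the screen's canonical values: seed = miRNA positions
#' 2-8 (G-U wobble allowed); 3' criterion = all of the last 8 positions
#' paired, or a run of >= `long_run` (9) consecutive pairs touching that
#' window; central loop strictly between `loop_min` (1) and `loop_max`
#' (6) nucleotides inclusive; binding energy at most `dg_max` (-16.0
#' kcal/mol, i.e. more stable than -16); hybrid abundance above
#' `rpm_min` (100 RPM) in the knockout condition and enrichment above
#' `fold_min` (4) over control.
#'
#' @param seed_span miRNA seed positions, inclusive (default `c(2, 8)`).
#' @param last_window width of the miRNA 3'-terminal window (default 8).
#' @param long_run run length satisfying the alternative 3' clause (default 9).
#' @param loop_min,loop_max admissible central-loop bounds in nt (1, 6).
#' @param dg_max maximum (least stable) admissible duplex energy, kcal/mol.
#' @param rpm_min minimum KO hybrid abundance in RPM (exclusive bound).
#' @param fold_min minimum KO/control enrichment (exclusive bound).
#' @param extension 3' extension of mapped target fragments, nt.
#' @param min_read_len minimum clean-read length, nt.
#' @param prefix_len miRNA-matching prefix length, nt.
#' @param umi_len random-nucleotide length at each read end.
#' @param merge_distance site-merging window on the transcript, nt.
#' @param rpm_pseudo pseudocount (RPM) in the fold-change ratio.
#' @param rpm_denominator `"all"` (total clean reads; default) or
#'   `"hybrid"` (hybrid reads only) per-condition RPM denominator.
#' @param kmer fragment-mapping k-mer size.
#' @param min_fragment minimum target-fragment length, nt.
#' @param adapter_min_overlap minimum adapter suffix overlap, nt.
#' @param tail_max maximum untemplated miRNA 3'-tail consumed, nt.
#' @param model the duplex [energy_model()].
#' @return a named list of class `screen_config`.
#' @export
screen_config <- function(seed_span = c(2L, 8L), last_window = 8L,
                          long_run = 9L, loop_min = 1L, loop_max = 6L,
                          dg_max = -16.0, rpm_min = 100, fold_min = 4,
                          extension = 25L, min_read_len = 18L,
                          prefix_len = 18L, umi_len = 4L,
                          merge_distance = 10L, rpm_pseudo = 0.1,
                          rpm_denominator = c("all", "hybrid"),
                          kmer = 12L, min_fragment = 12L,
                          adapter_min_overlap = 5L, tail_max = 3L,
                          model = energy_model()) {
  stopifnot(loop_min >= 1, loop_max < 7, rpm_min > 0, fold_min > 1)
  structure(list(
    seed_span = as.integer(seed_span), last_window = as.integer(last_window),
    long_run = as.integer(long_run), loop_min = as.integer(loop_min),
    loop_max = as.integer(loop_max), dg_max = dg_max, rpm_min = rpm_min,
    fold_min = fold_min, extension = as.integer(extension),
    min_read_len = as.integer(min_read_len),
    prefix_len = as.integer(prefix_len), umi_len = as.integer(umi_len),
    merge_distance = as.integer(merge_distance), rpm_pseudo = rpm_pseudo,
    rpm_denominator = match.arg(rpm_denominator), kmer = as.integer(kmer),
    min_fragment = as.integer(min_fragment),
    adapter_min_overlap = as.integer(adapter_min_overlap),
    tail_max = as.integer(tail_max), model = model
  ), class = "screen_config")
}

#' Seed criterion: miRNA positions 2-8 all paired (G-U wobble counts)
#' @param profile a [pairing_profile()].
#' @param config a [screen_config()].
#' @return logical.
#' @export
check_seed <- function(profile, config = screen_config()) {
  span <- config$seed_span
  if (length(profile$paired) < span[2])
    stop("miRNA shorter than the seed span")
  all(profile$paired[span[1]:span[2]])
}

.runs_true <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values],
             len = r$lengths[r$values])
}

#' 3'-end criterion: full pairing of the last 8 nt, or a 9-run touching it
#'
#' True iff (a) every miRNA position in the 3'-terminal window of
#' `last_window` (8) nucleotides is paired, or (b) some run of at least
#' `long_run` (9) consecutive paired miRNA positions includes a position
#' inside that window.
#'
#' @param profile a [pairing_profile()].
#' @param mirna_length miRNA length.
#' @param config a [screen_config()].
#' @return logical.
#' @export
check_three_prime <- function(profile, mirna_length = length(profile$paired),
                              config = screen_config()) {
  lo <- mirna_length - config$last_window + 1L
  if (all(profile$paired[lo:mirna_length])) return(TRUE)
  runs <- .runs_true(profile$paired)
  any(runs$len >= config$long_run & runs$end >= lo)
}

#' Central-loop length: max of miRNA-side and target-side unpaired counts
#' @param profile a [pairing_profile()].
#' @return numeric (possibly `Inf` when no helix lies 3' of the seed helix).
#' @export
central_loop_len <- function(profile) {
  unname(max(profile$central_loop))
}

#' Central-bulge criterion: loop strictly between 0 and 7 nt
#' @param profile a [pairing_profile()].
#' @param config a [screen_config()].
#' @return logical; perfect duplexes (loop 0) and seed-only structures
#'   (loop `Inf`) both fail.
#' @export
check_central <- function(profile, config = screen_config()) {
  len <- central_loop_len(profile)
  is.finite(len) && len >= config$loop_min && len <= config$loop_max
}

#' Classify one duplex against the four structural TDMD criteria
#'
#' @param duplex a `duplex_structure` from [fold_duplex()].
#' @param config a [screen_config()].
#' @return a one-row data.frame: `seed_ok`, `three_prime_ok`,
#'   `central_ok`, `energy_ok`, `central_loop_len`, `dg`, `n_pairs`,
#'   `is_candidate` (the conjunction of the four flags).
#' @export
classify_tdmd <- function(duplex, config = screen_config()) {
  profile <- pairing_profile(duplex, seed_span = config$seed_span,
                             last_window = config$last_window)
  seed_ok <- check_seed(profile, config)
  tp_ok <- check_three_prime(profile, duplex$mirna_length, config)
  central_ok <- check_central(profile, config)
  energy_ok <- duplex$dg <= config$dg_max
  data.frame(
    seed_ok = seed_ok, three_prime_ok = tp_ok, central_ok = central_ok,
    energy_ok = energy_ok, central_loop_len = central_loop_len(profile),
    dg = duplex$dg, n_pairs = nrow(duplex$pairs),
    is_candidate = seed_ok && tp_ok && central_ok && energy_ok
  )
}

#' Apply the two abundance criteria to classified hybrid sites
#'
#' High-confidence triggers are structural candidates whose hybrid
#' abundance in the knockout condition exceeds `rpm_min` RPM and whose
#' KO/control enrichment exceeds `fold_min`.
#'
#' @param site_summaries data.frame from [aggregate_hybrids()] (one row
#'   per merged site with `ko_rpm`, `control_rpm`, `fold_change`).
#' @param duplex_calls data.frame of [classify_tdmd()] rows aligned with
#'   `site_summaries`.
#' @param config a [screen_config()].
#' @return data.frame sorted by `ko_rpm` descending, with all structural
#'   flags, abundances, and `high_confidence`.
#' @export
screen_triggers <- function(site_summaries, duplex_calls,
                            config = screen_config()) {
  stopifnot(nrow(site_summaries) == nrow(duplex_calls))
  out <- cbind(as.data.frame(site_summaries), duplex_calls)
  out$high_confidence <- out$is_candidate &
    out$ko_rpm > config$rpm_min & out$fold_change > config$fold_min
  out[order(-out$ko_rpm), , drop = FALSE]
}
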