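#' Default nearest-neighbor energy model for intermolecular duplexes
#'
#' A deliberately simple, fully documented stacking model: every admissible
#' base pair carries a weight (`GC` = 3.0, `AU` = 2.0, `GU` = 1.0 kcal/mol)
#' and each pair of stacked adjacent pairs contributes minus the mean of the
#' two weights.  Bulges cost `bulge_open + bulge_per_nt * len`; internal
#' loops cost `iloop_open + iloop_per_nt * (l1 + l2) + iloop_asym * |l1 - l2|`;
#' duplex initiation costs `init`.  Unpaired overhangs outside the duplex are
#' free.  The maximal unpaired stretch on either side inside the duplex is
#' `max_loop` nucleotides.
#'
#' @param stack_gc,stack_au,stack_gu pair weights in kcal/mol (positive;
#'   a stack of two pairs contributes the negative mean of their weights).
#' @param bulge_open,bulge_per_nt bulge penalty parameters (kcal/mol).
#' @param iloop_open,iloop_per_nt,iloop_asym internal-loop penalty parameters.
#' @param init duplex initiation penalty (kcal/mol).
#' @param gu_allowed logical; admit G-U wobble pairs.
#' @param max_loop maximal unpaired stretch per strand inside the duplex (nt).
#' @return a named list of class `energy_model`.
#' @export
energy_model <- function(stack_gc = 3.0, stack_au = 2.0, stack_gu = 1.0,
                         bulge_open = 3.0, bulge_per_nt = 0.5,
                         iloop_open = 2.0, iloop_per_nt = 0.5,
                         iloop_asym = 0.5, init = 4.1,
                         gu_allowed = TRUE, max_loop = 10L) {
  stopifnot(stack_gc > 0, stack_au > 0, stack_gu > 0,
            bulge_open >= 0, bulge_per_nt >= 0,
            iloop_open >= 0, iloop_per_nt >= 0, iloop_asym >= 0,
            init >= 0, max_loop >= 1)
  structure(list(stack_gc = stack_gc, stack_au = stack_au, stack_gu = stack_gu,
                 bulge_open = bulge_open, bulge_per_nt = bulge_per_nt,
                 iloop_open = iloop_open, iloop_per_nt = iloop_per_nt,
                 iloop_asym = iloop_asym, init = init,
                 gu_allowed = gu_allowed, max_loop = as.integer(max_loop)),
            class = "energy_model")
}

.check_rna <- function(seq, what) {
  if (length(seq) != 1L || !is.character(seq))
    stop(what, " must be a single character string")
  if (grepl("[^ACGU]", seq))
    stop(what, " contains characters outside A/C/G/U")
  invisible(seq)
}

#' Fold a miRNA against a target site into the minimum-energy duplex
#'
#' Exact dynamic program over all antiparallel intermolecular pairings:
#' pair lists strictly increasing along the miRNA and strictly decreasing
#' along the target (both given 5'->3'), no pseudoknots, no intramolecular
#' structure.  Ties are broken towards more pairs, then the
#' lexicographically smallest pair list.  The empty structure (dg = 0) is
#' returned only when no base pair is admissible at all.
#'
#' @param mirna_seq miRNA sequence, 5'->3', RNA alphabet.
#' @param target_seq target site sequence, 5'->3', RNA alphabet.
#' @param model an [energy_model()].
#' @return a list of class `duplex_structure` with elements `pairs`
#'   (data.frame: `mirna_pos`, `target_pos`, `pair_type` in `"WC"`/`"GU"`),
#'   `paired` (logical vector over miRNA positions), `dg` (kcal/mol),
#'   `mirna_length`, `target_length`.
#' @export
fold_duplex <- function(mirna_seq, target_seq, model = energy_model()) {
  .check_rna(mirna_seq, "mirna_seq")
  .check_rna(target_seq, "target_seq")
  res <- .fold_duplex_cpp(mirna_seq, target_seq,
                          model$stack_gc, model$stack_au, model$stack_gu,
                          model$bulge_open, model$bulge_per_nt,
                          model$iloop_open, model$iloop_per_nt,
                          model$iloop_asym, model$init,
                          isTRUE(model$gu_allowed), model$max_loop)
  n <- nchar(mirna_seq)
  pairs <- data.frame(
    mirna_pos = res$mirna_pos,
    target_pos = res$target_pos,
    pair_type = ifelse(res$pair_class == 2L, "GU", "WC"),
    stringsAsFactors = FALSE
  )
  paired <- rep(FALSE, n)
  paired[pairs$mirna_pos] <- TRUE
  structure(list(pairs = pairs, paired = paired,
                 dg = if (nrow(pairs)) res$dg else 0,
                 mirna_length = n, target_length = nchar(target_seq)),
            class = "duplex_structure")
}

#' Derive helices and the central loop from a duplex structure
#'
#' Helices are maximal runs of pairs consecutive on both strands
#' (miRNA position stepping +1, target position stepping -1).  The
#' seed-proximal helix is the last helix overlapping miRNA positions
#' `seed_span[1]..seed_span[2]`; the central loop is measured between it
#' and the nearest helix 3' of it: `mirna_side` unpaired miRNA positions
#' strictly between the helices, `target_side` unpaired target positions
#' strictly between their target footprints.  When no helix lies 3' of
#' the seed helix the loop is `(0, 0)` if the seed helix itself runs into
#' the final `last_window` nucleotides of the miRNA (one continuous helix,
#' no central loop) and `(Inf, Inf)` otherwise (no 3' pairing at all).
#'
#' @param structure a `duplex_structure` from [fold_duplex()].
#' @param mirna_length miRNA length (defaults to the structure's).
#' @param seed_span integer pair, miRNA seed positions (default 2..8).
#' @param last_window width of the 3'-terminal window (default 8).
#' @return list with `paired`, `helices` (data.frame `mirna_from`,
#'   `mirna_to`, `target_hi`, `target_lo`), `central_loop`
#'   (`c(mirna_side, target_side)`, possibly `Inf`).
#' @export
pairing_profile <- function(structure, mirna_length = structure$mirna_length,
                            seed_span = c(2L, 8L), last_window = 8L) {
  pairs <- structure$pairs
  paired <- rep(FALSE, mirna_length)
  if (nrow(pairs)) paired[pairs$mirna_pos] <- TRUE

  helices <- NULL
  if (nrow(pairs)) {
    brk <- c(TRUE, diff(pairs$mirna_pos) != 1L | diff(pairs$target_pos) != -1L)
    grp <- cumsum(brk)
    helices <- do.call(rbind, lapply(split(seq_len(nrow(pairs)), grp), function(ix) {
      data.frame(mirna_from = pairs$mirna_pos[ix[1]],
                 mirna_to = pairs$mirna_pos[ix[length(ix)]],
                 target_hi = pairs$target_pos[ix[1]],
                 target_lo = pairs$target_pos[ix[length(ix)]])
    }))
    rownames(helices) <- NULL
  } else {
    helices <- data.frame(mirna_from = integer(0), mirna_to = integer(0),
                          target_hi = integer(0), target_lo = integer(0))
  }

  central <- c(mirna_side = Inf, target_side = Inf)
  seed_ix <- which(helices$mirna_from <= seed_span[2] &
                   helices$mirna_to >= seed_span[1])
  if (length(seed_ix)) {
    s <- seed_ix[length(seed_ix)]     # seed-proximal: nearest the center
    nxt <- which(helices$mirna_from > helices$mirna_to[s])
    if (length(nxt)) {
      nx <- nxt[1]
      central <- c(
        mirna_side = helices$mirna_from[nx] - helices$mirna_to[s] - 1,
        target_side = helices$target_lo[s] - helices$target_hi[nx] - 1
      )
    } else if (helices$mirna_to[s] >= mirna_length - last_window + 1L) {
      central <- c(mirna_side = 0, target_side = 0)
    }
  }

  list(paired = paired, helices = helices, central_loop = central)
}

#' @export
print.duplex_structure <- function(x, ...) {
  cat(sprintf("duplex_structure: %d pairs, dG = %.1f kcal/mol\n",
              nrow(x$pairs), x$dg))
  if (nrow(x$pairs)) {
    marks <- rep(" ", x$mirna_length)
    marks[x$pairs$mirna_pos] <- ifelse(x$pairs$pair_type == "GU", ":", "|")
    cat("5' miRNA  ", strsplit(paste(marks, collapse = ""), "")[[1]], "\n",
        sep = "")
  }
  invisible(x)
}
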