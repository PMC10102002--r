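#' Read a FASTA file
#'
#' Minimal strict FASTA reader for miRNA sets and transcriptomes.
#' Sequences are uppercased; when `rna = TRUE`, `T` is transliterated to
#' `U` so that all internal sequence logic is RNA-only.  Record order is
#' preserved.
#'
#' @param path file path.
#' @param rna transliterate T -> U (default TRUE).
#' @return data.frame with columns `id`, `sequence`.
#' @export
parse_fasta <- function(path, rna = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1])
    stop("FASTA format error: sequence data before first header in ", path)
  grp <- cumsum(is_hdr)
  ids <- sub("^>\\s*", "", sub("\\s.*$", "", lines[is_hdr]))
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]),
                 paste, character(1), collapse = "")
  # records with no sequence lines
  out <- character(max(grp))
  out[as.integer(names(seqs))] <- seqs
  out <- toupper(out)
  if (rna) out <- chartr("T", "U", out)
  data.frame(id = ids, sequence = out, stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#' @param ids,sequences character vectors of equal length.
#' @param path output path.
#' @export
write_fasta <- function(ids, sequences, path) {
  stopifnot(length(ids) == length(sequences))
  writeLines(as.vector(rbind(paste0(">", ids), sequences)), path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Strict 4-line-record FASTQ reader.  A truncated final record or a
#' sequence/quality length mismatch raises a format error naming the
#' record index.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
parse_fastq <- function(path) {
  lines <- readLines(path)
  if (!length(lines))
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  if (length(lines) %% 4L != 0L)
    stop("FASTQ format error: truncated record ",
         length(lines) %/% 4L + 1L, " in ", path)
  ix <- seq(1L, length(lines), by = 4L)
  ids <- lines[ix]
  if (any(!startsWith(ids, "@")))
    stop("FASTQ format error: record ",
         which(!startsWith(ids, "@"))[1], " header does not start with '@'")
  seqs <- lines[ix + 1L]
  quals <- lines[ix + 3L]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("FASTQ format error: sequence/quality length mismatch in record ",
         bad[1])
  data.frame(id = sub("^@", "", ids), sequence = toupper(seqs),
             quality = quals, stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#' @param ids,sequences character vectors; `quality` defaults to constant 'I'.
#' @param path output path.
#' @param quality optional quality strings (recycled 'I' runs if NULL).
#' @export
write_fastq <- function(ids, sequences, path, quality = NULL) {
  stopifnot(length(ids) == length(sequences))
  if (is.null(quality))
    quality <- strrep("I", nchar(sequences))
  writeLines(as.vector(rbind(paste0("@", ids), sequences, "+", quality)),
             path)
  invisible(path)
}

.hyb_cols <- c("read_id", "read_sequence", "dg",
               paste0("frag1_", c("gene_id", "read_start", "read_end",
                                  "gene_start", "gene_end", "score")),
               paste0("frag2_", c("gene_id", "read_start", "read_end",
                                  "gene_start", "gene_end", "score")))

#' Write hybrid records in the 15-column hyb-style dialect
#'
#' Internally all coordinates are 0-based half-open; the hyb dialect alone
#' is 1-based inclusive, so the conversion (`start + 1`, `end`) happens
#' here and is undone by [parse_hyb()].  `dg` is printed with one decimal.
#'
#' @param records data.frame with columns `read_id`, `read_sequence`,
#'   `dg`, and for each fragment `frag{1,2}_{gene_id,read_start,read_end,
#'   gene_start,gene_end,score}` (coordinates 0-based half-open).
#' @param path output path.
#' @export
write_hyb <- function(records, path) {
  stopifnot(all(.hyb_cols %in% names(records)))
  r <- records[, .hyb_cols]
  for (f in c("frag1_", "frag2_")) {
    for (col in paste0(f, c("read_start", "gene_start")))
      r[[col]] <- r[[col]] + 1L
    if (any(r[[paste0(f, "read_start")]] > r[[paste0(f, "read_end")]]))
      stop("invalid hyb record: read_start > read_end")
  }
  r$dg <- sprintf("%.1f", records$dg)
  utils::write.table(r, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse a 15-column hyb-style file back to 0-based half-open records
#' @param path file path.
#' @return data.frame in the layout accepted by [write_hyb()].
#' @export
parse_hyb <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- as.data.frame(setNames(rep(list(character(0)), 15), .hyb_cols))
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 15L))
    stop("hyb format error: line ", which(nf != 15L)[1],
         " has ", nf[nf != 15L][1], " columns (expected 15)")
  m <- do.call(rbind, fields)
  out <- data.frame(m, stringsAsFactors = FALSE)
  names(out) <- .hyb_cols
  out$dg <- as.numeric(out$dg)
  for (col in grep("_(read|gene)_(start|end)$|_score$", .hyb_cols, value = TRUE))
    out[[col]] <- as.integer(out[[col]])
  for (f in c("frag1_", "frag2_"))
    for (col in paste0(f, c("read_start", "gene_start")))
      out[[col]] <- out[[col]] - 1L
  out
}

#' Read a TSV count table (first column gene id, header = sample ids)
#' @param path file path.
#' @return integer matrix, genes x samples.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]]))
    stop("duplicate gene id in count table: ",
         df[[1]][duplicated(df[[1]])][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(is.na(suppressWarnings(m))) || any(m != round(m)))
    stop("non-integer cell in count table ", path)
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Write a count matrix as TSV
#' @param matrix integer matrix with rownames (genes) and colnames (samples).
#' @param path output path.
#' @param id_col name of the gene-id column (default `gene`).
#' @export
write_count_table <- function(matrix, path, id_col = "gene") {
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
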