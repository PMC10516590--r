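#' Read a (soft-masked) genome FASTA
#'
#' Case is preserved so that soft-masking survives a round trip.
#'
#' @param file FASTA path.
#' @return named character vector, one string per sequence.
#' @export
read_genome <- function(file) {
  seqs <- seqinr::read.fasta(file, as.string = TRUE, forceDNAtolower = FALSE,
                             seqonly = FALSE)
  out <- vapply(seqs, function(s) as.character(s)[1], character(1))
  names(out) <- names(seqs)
  out
}

#' Write a genome FASTA
#' @param seqs named character vector of sequences.
#' @param file output path.
#' @export
write_genome <- function(seqs, file) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = file, nbchar = 60)
  invisible(file)
}

#' Locate assembly gaps (runs of N)
#'
#' Finds maximal runs of `N`/`n` of at least `min_len` bases.
#'
#' @param sequence nucleotide string over `ACGTNacgtn`.
#' @param min_len minimum run length to report.
#' @param chrom chromosome name attached to the output intervals.
#' @return interval data frame of N-runs (0-based half-open, sorted).
#' @examples
#' find_n_runs("ACGTNNNNNNACGT", min_len = 6)
#' @export
find_n_runs <- function(sequence, min_len, chrom = NA_character_) {
  stopifnot(length(sequence) == 1, min_len >= 1)
  r <- charToRaw(sequence)
  ok <- r %in% charToRaw("ACGTNacgtn")
  if (!all(ok)) {
    bad <- which(!ok)
    stop("non-IUPAC character(s) at position(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (1-based): ", paste(rawToChar(r[utils::head(bad, 5)])))
  }
  isn <- r %in% charToRaw("Nn")
  if (!any(isn)) return(genomic_intervals())
  rl <- rle(isn)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths
  keep <- rl$values & rl$lengths >= min_len
  if (!any(keep)) return(genomic_intervals())
  genomic_intervals(chrom = chrom, start = starts[keep], end = ends[keep])
}

#' Read / write BED intervals
#'
#' BED3 or BED6, 0-based half-open, tab separated.
#'
#' @param file path.
#' @return interval data frame (with `name`, `score`, `strand` when BED6).
#' @export
read_bed <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (!ncol(df) %in% c(3, 6)) stop("expected BED3 or BED6: ", file)
  names(df) <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(df))]
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' @rdname read_bed
#' @param intervals interval data frame; `name`/`score`/`strand` columns are
#'   written when present (BED6), else BED3.
#' @export
write_bed <- function(intervals, file) {
  validate_intervals(intervals)
  cols <- c("chrom", "start", "end")
  if (all(c("name", "score", "strand") %in% names(intervals)))
    cols <- c(cols, "name", "score", "strand")
  utils::write.table(intervals[cols], file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read JASPAR-format position frequency matrices
#'
#' Accepts both the plain 4-row dialect and the bracketed dialect
#' (`A [ 1 2 3 ]`). Rows are taken in A, C, G, T order; the bracketed
#' dialect's row letters are honoured.
#'
#' @param file path to a JASPAR PFM text file (one or more records).
#' @return named list of PFMs; each a list with `id`, `name`, and a 4xL
#'   numeric `matrix` with rownames A, C, G, T.
#' @export
read_jaspar <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0) stop("no '>' headers found in ", file)
  out <- list()
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (k in seq_along(hdr_idx)) {
    hdr <- sub("^>\\s*", "", lines[hdr_idx[k]])
    toks <- strsplit(trimws(hdr), "[ \t]+")[[1]]
    id <- toks[1]
    name <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else id
    body <- lines[(hdr_idx[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(body) != 4) stop("PFM record '", id, "' must have 4 rows")
    rows <- lapply(body, function(l) {
      l2 <- trimws(l)
      letter <- NA_character_
      if (grepl("^[ACGTacgt]\\b", l2)) {
        letter <- toupper(substr(l2, 1, 1))
        l2 <- sub("^[ACGTacgt]", "", l2)
      }
      l2 <- gsub("[][]", " ", l2)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(l2), "[ \t]+")[[1]]))
      if (anyNA(vals)) stop("non-numeric PFM row in record '", id, "'")
      list(letter = letter, vals = vals)
    })
    lens <- vapply(rows, function(r) length(r$vals), 0L)
    if (length(unique(lens)) != 1) stop("ragged PFM rows in record '", id, "'")
    m <- do.call(rbind, lapply(rows, `[[`, "vals"))
    letters <- vapply(rows, `[[`, "", "letter")
    rownames(m) <- if (!anyNA(letters)) letters else c("A", "C", "G", "T")
    m <- m[c("A", "C", "G", "T"), , drop = FALSE]
    if (any(m < 0)) stop("negative PFM counts in record '", id, "'")
    out[[id]] <- structure(list(id = id, name = name, matrix = m),
                           class = "pfm")
  }
  out
}

#' Read a Newick tree
#' @param file path to a Newick file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(file) ape::read.tree(file)
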