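#' Alignment chains
#'
#' An `alignment_chain` is one pairwise alignment between a reference
#' chromosome and a query chromosome in the UCSC chain model: a scored
#' header plus an ordered list of ungapped blocks. Between consecutive
#' blocks, `dt` bases of reference and `dq` bases of query are unaligned.
#' Reference strand is always `+`; when the query strand is `-`, the query
#' coordinates are counted on the reverse strand, per the chain-format
#' convention. All coordinates are 0-based half-open.
#'
#' @param score non-negative alignment score.
#' @param ref_name,ref_size,ref_start,ref_end reference sequence and span.
#' @param query_name,query_size,query_strand,query_start,query_end query
#'   sequence and span (strand-local coordinates).
#' @param chain_id chain identifier (kept as character).
#' @param blocks data frame with columns `size`, `dt`, `dq`; `dt`/`dq` are
#'   `NA` on the final row.
#' @return an object of class `alignment_chain`.
#' @export
alignment_chain <- function(score, ref_name, ref_size, ref_start, ref_end,
                            query_name, query_size, query_strand,
                            query_start, query_end, chain_id, blocks) {
  ch <- structure(
    list(score = as.numeric(score), ref_name = ref_name,
         ref_size = as.numeric(ref_size), ref_strand = "+",
         ref_start = as.numeric(ref_start), ref_end = as.numeric(ref_end),
         query_name = query_name, query_size = as.numeric(query_size),
         query_strand = query_strand, query_start = as.numeric(query_start),
         query_end = as.numeric(query_end), chain_id = as.character(chain_id),
         blocks = blocks),
    class = "alignment_chain")
  validate_chain(ch)
  ch
}

validate_chain <- function(ch, line = NA) {
  where <- if (is.na(line)) "" else paste0(" (record starting at line ", line, ")")
  b <- ch$blocks
  n <- nrow(b)
  if (n < 1) stop("chain has no blocks", where)
  if (any(b$size <= 0)) stop("chain block size must be > 0", where)
  dt <- b$dt[-n]; dq <- b$dq[-n]
  if (n > 1 && (any(dt < 0) | any(dq < 0)))
    stop("negative dt/dq in chain", where)
  if (!is.na(b$dt[n]) || !is.na(b$dq[n]))
    stop("last chain block must not carry dt/dq", where)
  if (ch$score < 0) stop("negative chain score", where)
  if (!identical(ch$ref_strand, "+")) stop("reference strand must be '+'", where)
  if (!ch$query_strand %in% c("+", "-")) stop("bad query strand", where)
  ref_span <- sum(b$size) + sum(dt)
  q_span <- sum(b$size) + sum(dq)
  if (ref_span != ch$ref_end - ch$ref_start)
    stop("chain block sums do not match reference span", where)
  if (q_span != ch$query_end - ch$query_start)
    stop("chain block sums do not match query span", where)
  if (ch$ref_start < 0 || ch$ref_end > ch$ref_size ||
      ch$query_start < 0 || ch$query_end > ch$query_size)
    stop("chain span outside sequence bounds", where)
  invisible(ch)
}

#' Parse UCSC chain-format text
#'
#' @param text chain-format content: a single string, a character vector of
#'   lines, or a file path.
#' @return list of [alignment_chain()] objects, input order preserved.
#' @examples
#' parse_chain("chain 100 refChr1 1000 + 100 128 qChr1 900 + 200 226 1\n10 5 3\n13\n")
#' @export
parse_chain <- function(text) {
  lines <- if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    readLines(text) else unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- sub("[ \t\r]+$", "", lines)
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    if (!startsWith(lines[i], "chain"))
      stop("expected 'chain' header at line ", i)
    hdr <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(hdr) != 13)
      stop("malformed chain header at line ", i, ": expected 13 fields, got ",
           length(hdr))
    num <- suppressWarnings(as.numeric(hdr[c(2, 4, 6, 7, 9, 11, 12)]))
    if (anyNA(num)) stop("non-numeric field in chain header at line ", i)
    hline <- i
    i <- i + 1L
    sizes <- numeric(); dts <- numeric(); dqs <- numeric()
    repeat {
      if (i > n || !nzchar(lines[i])) stop("truncated chain record at line ", i)
      f <- suppressWarnings(as.numeric(strsplit(lines[i], "[ \t]+")[[1]]))
      if (anyNA(f) || !length(f) %in% c(1, 3))
        stop("malformed chain block line at line ", i)
      if (length(f) == 3) {
        sizes <- c(sizes, f[1]); dts <- c(dts, f[2]); dqs <- c(dqs, f[3])
        i <- i + 1L
      } else {
        sizes <- c(sizes, f[1]); i <- i + 1L; break
      }
    }
    blocks <- data.frame(size = sizes,
                         dt = c(dts, NA), dq = c(dqs, NA))
    ch <- structure(
      list(score = num[1], ref_name = hdr[3], ref_size = num[2],
           ref_strand = hdr[5], ref_start = num[3], ref_end = num[4],
           query_name = hdr[8], query_size = num[5], query_strand = hdr[10],
           query_start = num[6], query_end = num[7],
           chain_id = hdr[13], blocks = blocks),
      class = "alignment_chain")
    validate_chain(ch, line = hline)
    chains[[length(chains) + 1L]] <- ch
  }
  chains
}

#' Serialize chains to UCSC chain format
#'
#' Round-trips bit-exactly with [parse_chain()].
#'
#' @param chains list of [alignment_chain()] objects.
#' @param file optional path; if given, text is written there.
#' @return the chain-format text, invisibly when `file` is given.
#' @export
write_chain <- function(chains, file = NULL) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  rec <- vapply(chains, function(ch) {
    validate_chain(ch)
    hdr <- paste("chain", fmt(ch$score), ch$ref_name, fmt(ch$ref_size),
                 ch$ref_strand, fmt(ch$ref_start), fmt(ch$ref_end),
                 ch$query_name, fmt(ch$query_size), ch$query_strand,
                 fmt(ch$query_start), fmt(ch$query_end), ch$chain_id)
    b <- ch$blocks
    n <- nrow(b)
    body <- if (n > 1)
      c(paste(fmt(b$size[-n]), fmt(b$dt[-n]), fmt(b$dq[-n]), sep = "\t"),
        fmt(b$size[n]))
    else fmt(b$size[n])
    paste(c(hdr, body, ""), collapse = "\n")
  }, character(1))
  text <- paste0(paste(rec, collapse = "\n"), if (length(rec)) "\n" else "")
  if (length(rec) == 0) text <- ""
  if (!is.null(file)) {
    writeLines(text, file, sep = "")
    return(invisible(text))
  }
  text
}

#' Read a chain file
#' @param file path to a UCSC chain file.
#' @return list of [alignment_chain()] objects.
#' @export
read_chain <- function(file) parse_chain(readLines(file))

#' Reference intervals of a chain's aligned blocks
#'
#' @param chain an [alignment_chain()].
#' @return interval data frame of the ungapped block spans on the reference.
#' @export
chain_block_ref_intervals <- function(chain) {
  b <- chain$blocks
  n <- nrow(b)
  starts <- chain$ref_start + cumsum(c(0, b$size[-n] + b$dt[-n]))
  genomic_intervals(chrom = chain$ref_name, start = starts,
                    end = starts + b$size)
}

# query-side start coordinate of each block, in the chain's strand-local frame
chain_block_query_starts <- function(chain) {
  b <- chain$blocks
  n <- nrow(b)
  chain$query_start + cumsum(c(0, b$size[-n] + b$dq[-n]))
}

#' Convert strand-local query coordinates to forward-strand coordinates
#'
#' For `-`-strand chains the query coordinates count from the reverse
#' complement's origin; this maps a half-open strand-local interval back to
#' the forward strand of the query assembly.
#'
#' @param chain an [alignment_chain()].
#' @param start,end 0-based half-open strand-local query coordinates
#'   (`start == end` denotes a point).
#' @return numeric vector `c(start, end)` on the forward strand.
#' @export
query_forward_coords <- function(chain, start, end) {
  if (chain$query_strand == "+") return(c(start, end))
  c(chain$query_size - end, chain$query_size - start)
}
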