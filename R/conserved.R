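# reverse complement preserving case; N stays N
revcomp <- function(s) {
  chartr("ACGTacgtNn", "TGCAtgcaNn",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# aligned query sequence of block i (alignment orientation)
.block_query_seq <- function(chain, query_genome, block_i) {
  b <- chain$blocks
  qs <- chain_block_query_starts(chain)[block_i]
  size <- b$size[block_i]
  qseq <- query_genome[[chain$query_name]]
  if (is.null(qseq) || is.na(qseq))
    stop("query sequence '", chain$query_name, "' not found")
  if (chain$query_strand == "+") {
    substr(qseq, qs + 1, qs + size)
  } else {
    fwd <- query_forward_coords(chain, qs, qs + size)
    revcomp(substr(qseq, fwd[1] + 1, fwd[2]))
  }
}

#' Sliding-window percent identity over chain blocks
#'
#' For every ungapped block and every window size `w` not exceeding the
#' block length, computes the identity (matching bases / `w`,
#' case-insensitive, `N` never matches) of each window fully contained in
#' the block, advancing one base at a time. Windows never span inter-block
#' gaps, where identity would be undefined.
#'
#' @param chain an [alignment_chain()].
#' @param ref_genome,query_genome named character vectors of sequences.
#' @param window_sizes integer vector of window lengths.
#' @param species species label carried into the output.
#' @return data frame: `species`, `chain_id`, `chrom`, `start`, `end`,
#'   `window_size`, `identity`.
#' @export
score_windows <- function(chain, ref_genome, query_genome,
                          window_sizes = c(10, 25, 50, 100),
                          species = NA_character_) {
  rseq <- ref_genome[[chain$ref_name]]
  if (is.null(rseq) || is.na(rseq))
    stop("reference sequence '", chain$ref_name, "' not found")
  if (nchar(rseq) < chain$ref_end)
    stop("reference sequence shorter than chain span")
  blocks <- chain_block_ref_intervals(chain)
  out <- vector("list", nrow(blocks) * length(window_sizes))
  k <- 0L
  for (i in seq_len(nrow(blocks))) {
    size <- blocks$end[i] - blocks$start[i]
    ref_sub <- toupper(substr(rseq, blocks$start[i] + 1, blocks$end[i]))
    q_sub <- toupper(.block_query_seq(chain, query_genome, i))
    if (nchar(q_sub) != size)
      stop("query block length mismatch in chain ", chain$chain_id)
    rr <- charToRaw(ref_sub); qq <- charToRaw(q_sub)
    isN <- rr == charToRaw("N") | qq == charToRaw("N")
    match <- (rr == qq) & !isN
    cm <- c(0, cumsum(match))
    for (w in window_sizes) {
      if (w > size) next
      offs <- 0:(size - w)
      ident <- (cm[offs + w + 1] - cm[offs + 1]) / w
      k <- k + 1L
      out[[k]] <- data.frame(
        species = species, chain_id = chain$chain_id,
        chrom = chain$ref_name, start = blocks$start[i] + offs,
        end = blocks$start[i] + offs + w, window_size = w,
        identity = ident, stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(species = character(), chain_id = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      window_size = numeric(), identity = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out[seq_len(k)])
}

#' Call per-species conserved elements under a genome-wide coverage quota
#'
#' Windows (from all of a species' orthologous chains) are ranked by
#' identity, descending. The selection keeps the smallest number of
#' top-ranked windows whose merged, flattened union covers at least
#' `coverage_frac` of the reference, then atomically adds every window
#' tied with the last included identity value. Surviving windows are
#' merged within each chain at `merge_dist` to form the elements.
#'
#' @param windows data frame from [score_windows()] (one species).
#' @param genome_length total reference length in bp.
#' @param coverage_frac fraction of the reference the selection must cover.
#' @param merge_dist per-chain merge distance in bp.
#' @return data frame of elements: `species`, `chain_id`, `chrom`, `start`,
#'   `end`, `max_identity`.
#' @export
call_conserved_elements <- function(windows, genome_length,
                                    coverage_frac = 0.05, merge_dist = 20) {
  stopifnot(genome_length > 0, coverage_frac > 0)
  empty <- data.frame(species = character(), chain_id = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      max_identity = numeric(), stringsAsFactors = FALSE)
  if (nrow(windows) == 0) return(empty)
  quota <- coverage_frac * genome_length

  # walk identity tie classes from the top until the union reaches quota
  classes <- sort(unique(windows$identity), decreasing = TRUE)
  irl_all <- NULL
  covered <- 0
  cutoff <- NA_real_
  acc <- IRanges::IRangesList()
  for (cl in classes) {
    sub <- windows[windows$identity == cl, , drop = FALSE]
    irl <- .iv_split_ir(sub[c("chrom", "start", "end")])
    for (ch in names(irl)) {
      cur <- if (ch %in% names(acc)) acc[[ch]] else IRanges::IRanges()
      acc[[ch]] <- IRanges::reduce(c(cur, irl[[ch]]))
    }
    covered <- sum(vapply(as.list(acc), function(r) sum(IRanges::width(r)), 0))
    cutoff <- cl
    if (covered >= quota) break
  }
  if (covered < quota)
    warning("total window coverage (", covered,
            " bp) below quota; returning all windows")
  sel <- windows[windows$identity >= cutoff, , drop = FALSE]

  pieces <- lapply(split(seq_len(nrow(sel)), sel$chain_id), function(ii) {
    sub <- sel[ii, , drop = FALSE]
    m <- merge_intervals(sub[c("chrom", "start", "end")], merge_dist)
    # max identity of the windows contributing to each element
    mi <- vapply(seq_len(nrow(m)), function(j) {
      hit <- sub$chrom == m$chrom[j] & sub$start < m$end[j] & sub$end > m$start[j]
      max(sub$identity[hit])
    }, 0)
    data.frame(species = sub$species[1], chain_id = sub$chain_id[1],
               chrom = m$chrom, start = m$start, end = m$end,
               max_identity = mi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chain_id, out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}
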