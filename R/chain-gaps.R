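#' Extract chain gaps (candidate deletions) from a chain
#'
#' Every inter-block junction with `dt > 0` yields one gap: a reference
#' interval unaligned in the query. A gap is *single-sided* when the query
#' advances zero bases at the junction (`dq == 0`, a clean deletion) and
#' *double-sided* otherwise. Junctions with `dt == 0` (pure query
#' insertions) yield nothing. The query-side context is reported on the
#' forward strand of the query assembly: a point for single-sided gaps,
#' the unaligned query interval for double-sided ones.
#'
#' @param chain an [alignment_chain()].
#' @param species species label carried into the output.
#' @return data frame with columns `species`, `chain_id`, `chrom`, `start`,
#'   `end` (reference), `query_chrom`, `query_start`, `query_end`
#'   (forward strand; `query_start == query_end` for single-sided),
#'   `sided`, `valid` (initially `TRUE`).
#' @export
extract_chain_gaps <- function(chain, species = NA_character_) {
  b <- chain$blocks
  n <- nrow(b)
  empty <- data.frame(species = character(), chain_id = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      query_chrom = character(), query_start = numeric(),
                      query_end = numeric(), sided = character(),
                      valid = logical(), stringsAsFactors = FALSE)
  if (n < 2) return(empty)
  ref_starts <- chain$ref_start + cumsum(c(0, b$size[-n] + b$dt[-n]))
  q_starts <- chain$query_start + cumsum(c(0, b$size[-n] + b$dq[-n]))
  dt <- b$dt[-n]; dq <- b$dq[-n]
  keep <- which(dt > 0)
  if (length(keep) == 0) return(empty)
  gap_ref_start <- ref_starts[keep] + b$size[keep]
  q_local_start <- q_starts[keep] + b$size[keep]
  q_local_end <- q_local_start + dq[keep]
  fwd <- t(vapply(seq_along(keep), function(i)
    query_forward_coords(chain, q_local_start[i], q_local_end[i]),
    numeric(2)))
  data.frame(species = species, chain_id = chain$chain_id,
             chrom = chain$ref_name, start = gap_ref_start,
             end = gap_ref_start + dt[keep],
             query_chrom = chain$query_name,
             query_start = fwd[, 1], query_end = fwd[, 2],
             sided = ifelse(dq[keep] == 0, "single", "double"),
             valid = TRUE, stringsAsFactors = FALSE)
}

#' Invalidate chain gaps near assembly gaps
#'
#' A chain gap can be an artifact of incomplete assembly rather than a
#' genuine deletion. Gaps whose query-side context lies within `flank` bp
#' of an N-run of at least `n_run_min` bases in the query genome are
#' flagged invalid (distance 0 when the context overlaps the run).
#'
#' @param gaps data frame from [extract_chain_gaps()].
#' @param query_genome named character vector of the query assembly.
#' @param flank exclusion distance in bp.
#' @param n_run_min minimum N-run length that counts as an assembly gap.
#' @return `gaps` with the `valid` column updated.
#' @export
filter_gaps_near_assembly_gaps <- function(gaps, query_genome, flank = 100,
                                           n_run_min = 6) {
  if (nrow(gaps) == 0) return(gaps)
  for (qc in unique(gaps$query_chrom)) {
    if (!qc %in% names(query_genome))
      stop("query chromosome '", qc, "' absent from query genome")
    runs <- find_n_runs(query_genome[[qc]], n_run_min, chrom = qc)
    idx <- which(gaps$query_chrom == qc)
    if (nrow(runs) == 0) next
    for (i in idx) {
      a <- gaps$query_start[i]; b <- gaps$query_end[i]
      # distance between [a,b) and each run [s,e); 0 when overlapping
      d <- pmax(0, pmax(runs$start - b, a - runs$end))
      if (min(d) <= flank) gaps$valid[i] <- FALSE
    }
  }
  gaps
}

#' Merged per-chain deletion track
#'
#' Only valid gaps enter; merging happens within each (species, chain),
#' never across chains, at separation `max_dist`.
#'
#' @param gaps data frame from [extract_chain_gaps()] (after validation).
#' @param max_dist merge distance in bp.
#' @return data frame `species`, `chain_id`, `chrom`, `start`, `end`, sorted.
#' @export
merged_gap_track <- function(gaps, max_dist = 20) {
  gv <- gaps[gaps$valid, , drop = FALSE]
  if (nrow(gv) == 0)
    return(data.frame(species = character(), chain_id = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  key <- paste(gv$species, gv$chain_id, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(gv)), key), function(ii) {
    sub <- gv[ii, , drop = FALSE]
    m <- merge_intervals(sub[c("chrom", "start", "end")], max_dist)
    data.frame(species = sub$species[1], chain_id = sub$chain_id[1],
               chrom = m$chrom, start = m$start, end = m$end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$species, out$chain_id, out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}
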