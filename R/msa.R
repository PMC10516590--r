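#' Reference-anchored multiple alignment of a candidate interval
#'
#' Collates each species' orthologous sequence at the candidate's
#' reference coordinates from its pairwise chain. Columns are reference
#' positions: aligned query bases are placed at their reference position,
#' reference bases unaligned in a species (chain gaps) become `-`, and
#' query insertions — which have no reference column — are reported in a
#' side channel rather than columnized. Species whose chain does not span
#' the interval are listed as missing.
#'
#' @param candidate list or one-row data frame with `chrom`, `start`, `end`.
#' @param chains_by_species named list: one [alignment_chain()] per species
#'   (its orthologous chain at this locus).
#' @param genomes named list of query genomes (named character vectors).
#' @param ref_genome named character vector with the reference.
#' @param ref_name name of the reference row (default `"reference"`).
#' @return list with `msa` (named character vector of equal-length rows,
#'   reference first), `insertions` (named list of data frames `ref_pos`,
#'   `sequence`) and `missing` (species without a spanning chain).
#' @export
extract_condel_msa <- function(candidate, chains_by_species, genomes,
                               ref_genome, ref_name = "reference") {
  s <- candidate$start; e <- candidate$end; chrom <- candidate$chrom
  width <- e - s
  ref_row <- substr(ref_genome[[chrom]], s + 1, e)
  msa <- stats::setNames(ref_row, ref_name)
  insertions <- list()
  missing <- character()
  for (sp in names(chains_by_species)) {
    ch <- chains_by_species[[sp]]
    spans <- !is.null(ch) && identical(ch$ref_name, chrom) &&
      ch$ref_start <= s && ch$ref_end >= e
    if (!spans) { missing <- c(missing, sp); next }
    row <- rep("-", width)
    ins <- data.frame(ref_pos = numeric(), sequence = character(),
                      stringsAsFactors = FALSE)
    blocks <- chain_block_ref_intervals(ch)
    qstarts <- chain_block_query_starts(ch)
    b <- ch$blocks
    for (i in seq_len(nrow(blocks))) {
      bs <- blocks$start[i]; be <- blocks$end[i]
      os <- max(bs, s); oe <- min(be, e)
      if (os < oe) {
        qseq <- .block_query_seq(ch, genomes[[sp]], i)
        frag <- substr(qseq, os - bs + 1, oe - bs)
        row[(os - s + 1):(oe - s)] <- strsplit(frag, "", fixed = TRUE)[[1]]
      }
      # a query insertion at the junction after block i, inside the interval
      if (i < nrow(blocks) && !is.na(b$dq[i]) && b$dq[i] > 0 &&
          be >= s && be <= e) {
        q0 <- qstarts[i] + b$size[i]
        qseq_full <- genomes[[sp]][[ch$query_name]]
        iseq <- if (ch$query_strand == "+")
          substr(qseq_full, q0 + 1, q0 + b$dq[i])
        else {
          fwd <- query_forward_coords(ch, q0, q0 + b$dq[i])
          revcomp(substr(qseq_full, fwd[1] + 1, fwd[2]))
        }
        ins <- rbind(ins, data.frame(ref_pos = be, sequence = iseq,
                                     stringsAsFactors = FALSE))
      }
    }
    msa[sp] <- paste(row, collapse = "")
    if (nrow(ins)) insertions[[sp]] <- ins
  }
  list(msa = msa, insertions = insertions, missing = missing)
}

#' Write an MSA as FASTA
#' @param msa named character vector of aligned rows.
#' @param file output path.
#' @export
write_msa_fasta <- function(msa, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(msa)) writeLines(c(paste0(">", nm), msa[[nm]]), con)
  invisible(file)
}
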