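#' Gene models
#'
#' A gene model carries one or more transcripts, each a span with exon
#' blocks. The canonical transcript is the longest (by genomic span), with
#' ties broken by lexicographic transcript id; it anchors the TSS used by
#' the association scan and the exonic bases used by the orthology filter.
#'
#' @param gene_id gene identifier.
#' @param chrom reference chromosome.
#' @param strand `"+"` or `"-"`.
#' @param transcripts list; each element a list with `tx_id`, `tx_start`,
#'   `tx_end` (0-based half-open) and `exons`, an interval data frame.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  stopifnot(strand %in% c("+", "-"), length(transcripts) >= 1)
  for (tx in transcripts) {
    stopifnot(tx$tx_start < tx$tx_end)
    if (nrow(tx$exons) > 0 &&
        (min(tx$exons$start) < tx$tx_start || max(tx$exons$end) > tx$tx_end))
      stop("exons outside transcript span for gene ", gene_id)
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = transcripts),
            class = "gene_model")
}

#' @rdname gene_model
#' @param gene a `gene_model`.
#' @return `canonical_transcript()`: the canonical transcript element.
#' @export
canonical_transcript <- function(gene) {
  spans <- vapply(gene$transcripts, function(tx) tx$tx_end - tx$tx_start, 0)
  ids <- vapply(gene$transcripts, `[[`, "", "tx_id")
  ord <- order(-spans, ids)
  gene$transcripts[[ord[1]]]
}

#' Transcription start site of the canonical transcript
#' @param gene a `gene_model`.
#' @return 0-based position of the TSS (`tx_start` on `+`, `tx_end - 1` on `-`).
#' @export
gene_tss <- function(gene) {
  tx <- canonical_transcript(gene)
  if (gene$strand == "+") tx$tx_start else tx$tx_end - 1
}

#' Read gene models from a BED12-like TSV
#'
#' Columns: chrom, tx_start, tx_end, gene_id, tx_id, strand, block_sizes,
#' block_starts (comma lists; block starts relative to tx_start). One row
#' per transcript.
#'
#' @param file path.
#' @return named list of [gene_model()] objects.
#' @export
read_gene_models <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "tx_start", "tx_end", "gene_id", "tx_id", "strand",
            "block_sizes", "block_starts")
  if (!all(need %in% names(df)))
    stop("gene model table must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (g in unique(df$gene_id)) {
    rows <- df[df$gene_id == g, , drop = FALSE]
    txs <- lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      bs <- as.numeric(strsplit(r$block_sizes, ",")[[1]])
      bo <- as.numeric(strsplit(r$block_starts, ",")[[1]])
      list(tx_id = r$tx_id, tx_start = r$tx_start, tx_end = r$tx_end,
           exons = genomic_intervals(chrom = r$chrom,
                                     start = r$tx_start + bo,
                                     end = r$tx_start + bo + bs))
    })
    out[[g]] <- gene_model(g, rows$chrom[1], rows$strand[1], txs)
  }
  out
}

#' @rdname read_gene_models
#' @param genes named list of gene models.
#' @export
write_gene_models <- function(genes, file) {
  rows <- do.call(rbind, lapply(genes, function(g) {
    do.call(rbind, lapply(g$transcripts, function(tx) {
      data.frame(chrom = g$chrom, tx_start = tx$tx_start, tx_end = tx$tx_end,
                 gene_id = g$gene_id, tx_id = tx$tx_id, strand = g$strand,
                 block_sizes = paste(tx$exons$end - tx$exons$start, collapse = ","),
                 block_starts = paste(tx$exons$start - tx$tx_start, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
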