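#' Overlap-weighted chain score for a gene
#'
#' A chain's candidacy as the orthologous alignment for a gene is its
#' alignment score multiplied by the fraction of the gene's canonical
#' exonic bases covered by the chain's aligned blocks.
#'
#' @param gene a [gene_model()].
#' @param chain an [alignment_chain()] on the same reference chromosome.
#' @return non-negative number; 0 when gene and chain do not overlap.
#' @export
score_gene_chain_overlap <- function(gene, chain) {
  if (!identical(gene$chrom, chain$ref_name)) return(0)
  exons <- merge_intervals(canonical_transcript(gene)$exons, 0)
  if (nrow(exons) == 0) return(0)
  blocks <- chain_block_ref_intervals(chain)
  ov <- intersect_intervals(exons, blocks)
  covered <- if (nrow(ov)) sum(ov$end - ov$start) else 0
  chain$score * covered / sum(exons$end - exons$start)
}

#' Select the orthology-confident chain for one gene and species
#'
#' The best-overlap chain is accepted as *confident* when either the
#' best-to-second score ratio is at least `ratio_thresh` (a sole
#' overlapping chain counts as ratio infinity), or at least
#' `synteny_thresh` of the nearest flanking genes share the same best
#' chain (gene-in-synteny). Otherwise the call is *ambiguous*; with no
#' overlapping chain at all it is *unmapped*.
#'
#' @param gene a [gene_model()].
#' @param chains list of [alignment_chain()] objects from one query species.
#' @param ratio_thresh best/second score ratio needed for confidence.
#' @param synteny_thresh number of flanking-gene agreements needed.
#' @param neighbor_best_chains character vector: the best chain id of each
#'   of the nearest flanking genes considered (up to 10 per side).
#' @return list with `gene_id`, `chain_id` (or `NA`), `confidence`
#'   (`confident`/`ambiguous`/`unmapped`), `best_score`, `second_score`,
#'   `synteny_support`.
#' @export
select_orthologous_chain <- function(gene, chains, ratio_thresh = 10,
                                     synteny_thresh = 10,
                                     neighbor_best_chains = character()) {
  scores <- vapply(chains, function(ch) score_gene_chain_overlap(gene, ch), 0)
  if (length(scores) == 0 || all(scores <= 0))
    return(list(gene_id = gene$gene_id, chain_id = NA_character_,
                confidence = "unmapped", best_score = 0, second_score = 0,
                synteny_support = 0L))
  ord <- order(-scores)
  best <- ord[1]
  best_score <- scores[best]
  second_score <- if (length(scores) > 1) scores[ord[2]] else 0
  best_id <- chains[[best]]$chain_id
  support <- sum(neighbor_best_chains == best_id, na.rm = TRUE)
  ratio_ok <- second_score == 0 || best_score / second_score >= ratio_thresh
  synteny_ok <- support >= synteny_thresh
  list(gene_id = gene$gene_id, chain_id = best_id,
       confidence = if (ratio_ok || synteny_ok) "confident" else "ambiguous",
       best_score = best_score, second_score = second_score,
       synteny_support = as.integer(support))
}

#' Orthology calls for all genes of one species
#'
#' Two-pass procedure: first the best-overlap chain per gene, then
#' confidence using score ratio and gene-in-synteny support counted over
#' the `n_neighbors` nearest flanking genes on each side (by TSS order on
#' the same chromosome).
#'
#' @param genes named list of [gene_model()] objects.
#' @param chains list of [alignment_chain()] objects for the species.
#' @param species species label carried into the output.
#' @param ratio_thresh,synteny_thresh confidence thresholds.
#' @param n_neighbors flanking genes considered per side.
#' @return data frame with one row per gene: `gene_id`, `species`,
#'   `chain_id`, `confidence`, `best_score`, `second_score`,
#'   `synteny_support`.
#' @export
orthology_map_species <- function(genes, chains, species = NA_character_,
                                  ratio_thresh = 10, synteny_thresh = 10,
                                  n_neighbors = 10) {
  score_mat <- vapply(chains, function(ch)
    vapply(genes, function(g) score_gene_chain_overlap(g, ch), 0),
    numeric(length(genes)))
  score_mat <- matrix(score_mat, nrow = length(genes))
  chain_ids <- vapply(chains, `[[`, "", "chain_id")
  best_idx <- apply(score_mat, 1, function(s)
    if (all(s <= 0)) NA_integer_ else which.max(s))
  best_ids <- ifelse(is.na(best_idx), NA_character_, chain_ids[best_idx])
  names(best_ids) <- names(genes)

  # gene order along each chromosome for neighbor lookup
  chrom <- vapply(genes, `[[`, "", "chrom")
  tss <- vapply(genes, gene_tss, 0)
  calls <- lapply(seq_along(genes), function(i) {
    same <- which(chrom == chrom[i] & names(genes) != names(genes)[i])
    if (length(same)) {
      d <- abs(tss[same] - tss[i])
      left <- same[tss[same] < tss[i]][order(d[tss[same] < tss[i]])]
      right <- same[tss[same] >= tss[i]][order(d[tss[same] >= tss[i]])]
      nb <- c(utils::head(left, n_neighbors), utils::head(right, n_neighbors))
    } else nb <- integer()
    res <- select_orthologous_chain(
      genes[[i]], chains, ratio_thresh, synteny_thresh,
      neighbor_best_chains = best_ids[nb])
    data.frame(gene_id = res$gene_id, species = species,
               chain_id = res$chain_id, confidence = res$confidence,
               best_score = res$best_score, second_score = res$second_score,
               synteny_support = res$synteny_support,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, calls)
}

#' Orthology calls across all species
#'
#' @param genes named list of [gene_model()] objects.
#' @param chains_by_species named list: per species, a list of chains.
#' @inheritParams orthology_map_species
#' @return combined data frame of per-(gene, species) orthology calls.
#' @export
orthology_map <- function(genes, chains_by_species, ratio_thresh = 10,
                          synteny_thresh = 10, n_neighbors = 10) {
  do.call(rbind, lapply(names(chains_by_species), function(sp)
    orthology_map_species(genes, chains_by_species[[sp]], species = sp,
                          ratio_thresh = ratio_thresh,
                          synteny_thresh = synteny_thresh,
                          n_neighbors = n_neighbors)))
}
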