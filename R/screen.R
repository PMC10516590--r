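#' Per-gene association scan window
#'
#' The screen examines the interval spanning `flank` bp on each side of
#' the canonical transcript's TSS. With the default 200 kb flank the
#' unclipped window is 400,001 bp (the TSS base plus 200,000 on either
#' side); windows are clipped to the chromosome.
#'
#' @param gene a [gene_model()].
#' @param flank bp scanned on each side of the TSS.
#' @param chrom_length reference chromosome length, for clipping.
#' @return list `chrom`, `start`, `end` (0-based half-open).
#' @export
gene_scan_window <- function(gene, flank = 200000, chrom_length = Inf) {
  t <- gene_tss(gene)
  if (t < 0 || t >= chrom_length)
    stop("TSS of gene ", gene$gene_id, " outside chromosome")
  list(chrom = gene$chrom, start = max(0, t - flank),
       end = min(chrom_length, t + flank + 1))
}

#' Genes scorable by the screen
#'
#' A gene enters the screen only when it maps confidently to enough
#' trait-complete outgroups and enough trait-reduced targets.
#'
#' @param orthology_calls data frame from [orthology_map()].
#' @param species_config data frame with `species`, `role`
#'   (`reference`/`outgroup`/`target`), `clade`, `screened`.
#' @param min_outgroups,min_targets minimum confident mappings per role.
#' @return character vector of scorable gene ids.
#' @export
scorable_genes <- function(orthology_calls, species_config,
                           min_outgroups = 17, min_targets = 5) {
  conf <- orthology_calls[orthology_calls$confidence == "confident", ,
                          drop = FALSE]
  role <- species_config$role[match(conf$species, species_config$species)]
  genes <- unique(orthology_calls$gene_id)
  keep <- vapply(genes, function(g) {
    sub <- role[conf$gene_id == g]
    sum(sub == "outgroup") >= min_outgroups && sum(sub == "target") >= min_targets
  }, logical(1))
  genes[keep]
}

#' Clade-consensus target deletions within a window
#'
#' Maximal intervals where, for *every* screened target clade, at least
#' `ceiling(frac * clade_size)` of the clade's species show a valid chain
#' gap covering the base. Species without an orthologous chain at the gene
#' contribute no gap (the denominator stays the full clade).
#'
#' @param window list `chrom`, `start`, `end` from [gene_scan_window()].
#' @param gap_tracks named list: per species, an interval data frame of its
#'   merged valid gaps on the gene's orthologous chain.
#' @param clades named list: per screened clade, its species vector.
#' @param frac consensus fraction per clade.
#' @return interval data frame of the consensus deletions (clipped to window).
#' @export
target_deletion_consensus <- function(window, gap_tracks, clades,
                                      frac = 2 / 3) {
  stopifnot(length(clades) >= 1)
  per_clade <- lapply(names(clades), function(cl) {
    members <- clades[[cl]]
    if (length(members) == 0) stop("clade '", cl, "' has no species")
    need <- ceiling(frac * length(members))
    tracks <- lapply(members, function(sp) {
      t <- gap_tracks[[sp]]
      if (is.null(t) || nrow(t) == 0) return(genomic_intervals())
      clip_intervals(t[c("chrom", "start", "end")], window)
    })
    names(tracks) <- members
    suppressWarnings(coverage_count(tracks, min_species = need, min_span = 1))
  })
  out <- per_clade[[1]]
  for (p in per_clade[-1]) out <- intersect_intervals(out, p)
  clip_intervals(out, window)
}

#' Intersect consensus deletions with deep conservation
#'
#' Raw candidates are intersection pieces of at least `min_raw` bp between
#' the clade-consensus deletions and the regions conserved in enough
#' outgroups; raw candidates within `merge_dist` bp merge, and merged
#' pieces of at least `min_final` bp become final candidates.
#'
#' @param window list `chrom`, `start`, `end`.
#' @param deletion_consensus interval data frame
#'   (from [target_deletion_consensus()]).
#' @param conserved_cov interval data frame of bases conserved in at least
#'   the required number of outgroups (from [coverage_count()]).
#' @param merge_dist,min_raw,min_final bp thresholds.
#' @return list with interval data frames `raw` and `final`.
#' @export
call_condels <- function(window, deletion_consensus, conserved_cov,
                         merge_dist = 20, min_raw = 20, min_final = 50) {
  raw <- intersect_intervals(clip_intervals(deletion_consensus, window),
                             clip_intervals(conserved_cov, window))
  if (nrow(raw)) raw <- raw[raw$end - raw$start >= min_raw, , drop = FALSE]
  merged <- merge_intervals(raw, merge_dist)
  final <- if (nrow(merged))
    merged[merged$end - merged$start >= min_final, , drop = FALSE]
  else merged
  rownames(raw) <- NULL; rownames(final) <- NULL
  list(raw = raw, final = final)
}

#' Genotype-phenotype violation filter over outgroups
#'
#' A candidate is discarded when more than `max_violations` scorable
#' outgroups — those whose confident orthologous chain spans the candidate
#' entirely — carry a valid chain gap overlapping it.
#'
#' @param candidates interval data frame of final candidates.
#' @param outgroup_gap_tracks named list per outgroup species: interval data
#'   frame of merged valid gaps on its orthologous chain.
#' @param outgroup_chain_spans named list per outgroup species: list
#'   `chrom`, `start`, `end` of the confident chain's reference span
#'   (`NULL` when the species has no confident chain for the gene).
#' @param max_violations maximum tolerated violating outgroups.
#' @return `candidates` with a `violations` column, filtered.
#' @export
outgroup_violation_filter <- function(candidates, outgroup_gap_tracks,
                                      outgroup_chain_spans,
                                      max_violations = 1) {
  if (nrow(candidates) == 0) {
    candidates$violations <- integer(0)
    return(candidates)
  }
  viol <- vapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, , drop = FALSE]
    v <- 0L
    for (sp in names(outgroup_chain_spans)) {
      span <- outgroup_chain_spans[[sp]]
      if (is.null(span)) next
      scorable <- identical(span$chrom, cand$chrom) &&
        span$start <= cand$start && span$end >= cand$end
      if (!scorable) next
      t <- outgroup_gap_tracks[[sp]]
      if (is.null(t) || nrow(t) == 0) next
      if (any(overlaps_any(cand[c("chrom", "start", "end")],
                           t[c("chrom", "start", "end")]))) v <- v + 1L
    }
    v
  }, integer(1))
  candidates$violations <- viol
  out <- candidates[viol <= max_violations, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse identical candidates discovered via different genes
#'
#' Interval identity is exact (`chrom`, `start`, `end`); the linked-gene
#' set of a collapsed record is the union. Overlapping but unequal
#' intervals are kept distinct.
#'
#' @param candidates data frame with at least `chrom`, `start`, `end`,
#'   `gene_id`.
#' @return deduplicated data frame with a comma-separated `linked_genes`
#'   column and `n_linked_genes`.
#' @export
deduplicate_condels <- function(candidates) {
  if (nrow(candidates) == 0) {
    candidates$linked_genes <- character(0)
    candidates$n_linked_genes <- integer(0)
    return(candidates)
  }
  key <- paste(candidates$chrom, candidates$start, candidates$end, sep = ":")
  pieces <- lapply(split(seq_len(nrow(candidates)), key), function(ii) {
    sub <- candidates[ii, , drop = FALSE]
    rec <- sub[1, setdiff(names(sub), "gene_id"), drop = FALSE]
    rec$linked_genes <- paste(sort(unique(sub$gene_id)), collapse = ",")
    rec$n_linked_genes <- length(unique(sub$gene_id))
    rec
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default screen thresholds
#'
#' Every threshold of the screen, in one place: minimum confident
#' outgroup/target mappings per gene, the per-clade deletion consensus
#' fraction, scan flank, window sizes and conservation coverage quota,
#' merge distances, raw and final size cut-offs, assembly-gap exclusion
#' parameters, and orthology-confidence thresholds.
#'
#' @param ... overrides of the defaults.
#' @return named list of screen parameters.
#' @export
screen_config <- function(...) {
  cfg <- list(min_outgroups = 17, min_targets = 5, clade_frac = 2 / 3,
              flank = 200000, window_sizes = c(10, 25, 50, 100),
              coverage_frac = 0.05, merge_dist = 20, min_raw = 20,
              min_final = 50, max_violations = 1, assembly_flank = 100,
              n_run_min = 6, ratio_thresh = 10, synteny_thresh = 10,
              n_neighbors = 10)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown screen_config option(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

# minimum per-base outgroup conservation count across a candidate
.min_outgroup_cov <- function(cand, element_tracks) {
  counts <- NULL
  width <- cand$end - cand$start
  per_base <- integer(width)
  for (sp in names(element_tracks)) {
    t <- element_tracks[[sp]]
    if (is.null(t) || nrow(t) == 0) next
    sub <- clip_intervals(t[c("chrom", "start", "end")],
                          list(chrom = cand$chrom, start = cand$start,
                               end = cand$end))
    if (nrow(sub) == 0) return(0L)
    cov <- logical(width)
    for (j in seq_len(nrow(sub)))
      cov[(sub$start[j] - cand$start + 1):(sub$end[j] - cand$start)] <- TRUE
    per_base <- per_base + cov
  }
  as.integer(min(per_base))
}

#' Run the conserved-sequence-deletion screen
#'
#' Executes the full association scan on an in-memory bundle: orthology
#' filtering, chain-gap deletion calling with assembly-gap exclusion,
#' per-outgroup conserved-element detection under the coverage quota, the
#' per-gene clade-consensus scan, violation filtering and deduplication.
#'
#' @param bundle list with components `ref_genome` (named character
#'   vector), `genomes` (named list of query genomes), `chains_by_species`
#'   (named list of chain lists), `genes` (named list of [gene_model()]s)
#'   and `species_config` (data frame `species`, `role`, `clade`,
#'   `screened`), e.g. from [simulate_condel_bundle()].
#' @param config list from [screen_config()].
#' @return object of class `condel_screen`: `candidates` (deduplicated
#'   final candidates), `per_gene` results, `orthology` calls, `elements`
#'   per outgroup, `conserved_cov`, `gap_tracks`, `funnel` stage counts and
#'   the `config` used.
#' @export
condel_screen <- function(bundle, config = screen_config()) {
  sc <- bundle$species_config
  stopifnot(sum(sc$role == "reference") == 1)
  screened <- unique(sc$clade[sc$role == "target" & sc$screened])
  if (length(screened) < 2)
    stop("need at least two screened target clades")
  clades <- lapply(screened, function(cl) sc$species[sc$clade == cl & sc$role == "target"])
  names(clades) <- screened
  outgroups <- sc$species[sc$role == "outgroup"]
  targets <- sc$species[sc$role == "target"]
  genome_length <- sum(nchar(bundle$ref_genome))
  chrom_lengths <- nchar(bundle$ref_genome)

  # 1. orthology
  orth <- orthology_map(bundle$genes, bundle$chains_by_species,
                        ratio_thresh = config$ratio_thresh,
                        synteny_thresh = config$synteny_thresh,
                        n_neighbors = config$n_neighbors)
  genes_ok <- scorable_genes(orth, sc, config$min_outgroups, config$min_targets)

  # 2. chain gaps per non-reference species, assembly-gap-filtered, merged
  gap_tracks <- list()
  for (sp in c(targets, outgroups)) {
    chains <- bundle$chains_by_species[[sp]]
    if (is.null(chains)) next
    gaps <- do.call(rbind, lapply(chains, extract_chain_gaps, species = sp))
    if (is.null(gaps) || nrow(gaps) == 0) next
    gaps <- filter_gaps_near_assembly_gaps(gaps, bundle$genomes[[sp]],
                                           flank = config$assembly_flank,
                                           n_run_min = config$n_run_min)
    gap_tracks[[sp]] <- merged_gap_track(gaps, max_dist = config$merge_dist)
  }

  # 3. conserved elements per outgroup, on its orthology-confident chains
  elements <- list()
  for (sp in outgroups) {
    conf_ids <- unique(orth$chain_id[orth$species == sp &
                                       orth$confidence == "confident"])
    chains <- bundle$chains_by_species[[sp]]
    chains <- chains[vapply(chains, `[[`, "", "chain_id") %in% conf_ids]
    if (length(chains) == 0) next
    win <- do.call(rbind, lapply(chains, score_windows,
                                 ref_genome = bundle$ref_genome,
                                 query_genome = bundle$genomes[[sp]],
                                 window_sizes = config$window_sizes,
                                 species = sp))
    elements[[sp]] <- call_conserved_elements(
      win, genome_length, coverage_frac = config$coverage_frac,
      merge_dist = config$merge_dist)
  }
  conserved_cov <- coverage_count(
    lapply(elements, function(e) e[c("chrom", "start", "end")]),
    min_species = config$min_outgroups, min_span = config$min_raw)

  # lookups: confident chain per (gene, species)
  conf <- orth[orth$confidence == "confident", , drop = FALSE]
  chain_by <- function(sp, id) {
    for (ch in bundle$chains_by_species[[sp]])
      if (identical(ch$chain_id, id)) return(ch)
    NULL
  }

  # 4. per-gene scan
  per_gene <- list()
  all_cands <- list()
  for (g in genes_ok) {
    gene <- bundle$genes[[g]]
    window <- gene_scan_window(gene, flank = config$flank,
                               chrom_length = chrom_lengths[[gene$chrom]])
    gene_conf <- conf[conf$gene_id == g, , drop = FALSE]
    # per-species gaps restricted to the gene's orthologous chain
    sp_gaps <- list(); sp_spans <- list()
    for (i in seq_len(nrow(gene_conf))) {
      sp <- gene_conf$species[i]; id <- gene_conf$chain_id[i]
      ch <- chain_by(sp, id)
      if (is.null(ch)) next
      sp_spans[[sp]] <- list(chrom = ch$ref_name, start = ch$ref_start,
                             end = ch$ref_end)
      t <- gap_tracks[[sp]]
      if (!is.null(t))
        sp_gaps[[sp]] <- t[t$chain_id == id, c("chrom", "start", "end"),
                           drop = FALSE]
    }
    consensus <- target_deletion_consensus(window, sp_gaps, clades,
                                           frac = config$clade_frac)
    calls <- call_condels(window, consensus, conserved_cov,
                          merge_dist = config$merge_dist,
                          min_raw = config$min_raw,
                          min_final = config$min_final)
    og_spans <- sp_spans[names(sp_spans) %in% outgroups]
    og_gaps <- sp_gaps[names(sp_gaps) %in% outgroups]
    final <- outgroup_violation_filter(calls$final, og_gaps, og_spans,
                                       max_violations = config$max_violations)
    per_gene[[g]] <- list(window = window, consensus = consensus,
                          raw = calls$raw, final = final)
    if (nrow(final)) {
      final$gene_id <- g
      # per-clade support and conservation depth annotations
      final$length <- final$end - final$start
      for (cl in names(clades)) {
        cnt <- vapply(seq_len(nrow(final)), function(i) {
          sum(vapply(clades[[cl]], function(sp) {
            t <- sp_gaps[[sp]]
            !is.null(t) && nrow(t) > 0 &&
              any(overlaps_any(final[i, c("chrom", "start", "end")], t))
          }, logical(1)))
        }, integer(1))
        final[[paste0("support_", cl)]] <- cnt
      }
      final$conservation_count <- vapply(seq_len(nrow(final)), function(i)
        .min_outgroup_cov(final[i, , drop = FALSE], elements), integer(1))
      all_cands[[g]] <- final
    }
  }
  cand_df <- if (length(all_cands)) do.call(rbind, all_cands) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               violations = integer(), gene_id = character(),
               length = numeric(), conservation_count = integer(),
               stringsAsFactors = FALSE)
  candidates <- deduplicate_condels(cand_df)

  structure(list(
    candidates = candidates, per_gene = per_gene, orthology = orth,
    elements = elements, conserved_cov = conserved_cov,
    gap_tracks = gap_tracks, config = config, species_config = sc,
    funnel = c(genes_total = length(bundle$genes),
               genes_scorable = length(genes_ok),
               candidate_records = nrow(cand_df),
               unique_candidates = nrow(candidates))),
    class = "condel_screen")
}

#' @export
print.condel_screen <- function(x, ...) {
  cat("Conserved-sequence-deletion screen\n")
  cat(sprintf("  genes: %d scorable of %d\n", x$funnel[["genes_scorable"]],
              x$funnel[["genes_total"]]))
  cat(sprintf("  unique candidates: %d (from %d per-gene records)\n",
              x$funnel[["unique_candidates"]], x$funnel[["candidate_records"]]))
  invisible(x)
}

#' @method summary condel_screen
#' @export
summary.condel_screen <- function(object, ...) {
  cat("Conserved-sequence-deletion screen\n\nThresholds:\n")
  cfg <- object$config
  cat(sprintf("  outgroups >= %d, targets >= %d, clade consensus >= %s\n",
              cfg$min_outgroups, cfg$min_targets,
              format(cfg$clade_frac, digits = 3)))
  cat(sprintf("  raw >= %d bp, final >= %d bp, merge <= %d bp, violations <= %d\n",
              cfg$min_raw, cfg$min_final, cfg$merge_dist, cfg$max_violations))
  cat("\nFunnel:\n")
  print(object$funnel)
  if (nrow(object$candidates)) {
    cat("\nCandidates:\n")
    print(utils::head(as.data.frame(object$candidates), 10))
  }
  invisible(object)
}
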