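#' Synthetic screen configuration
#'
#' Describes a complete synthetic study: a random reference chromosome
#' carrying deterministically placed genes, planted conserved elements and
#' planted clade-specific deletions; outgroup and target genomes derived
#' from the reference by two-class substitution noise (background vs
#' conserved); and one whole-chromosome alignment chain per species
#' emitted directly from the known simulated alignment, so the screen is
#' isolated from aligner behaviour.
#'
#' Planted-feature coordinates are a deterministic function of the
#' configuration (not of the seed): features sit on an even grid along
#' the chromosome, with deletion lengths spanning `condel_length_range`
#' evenly. Only the neutral noise (reference composition, substitutions,
#' optional indels) consumes random numbers, so different seeds move the
#' noise but never the truth.
#'
#' @param ref_length reference chromosome length in bp.
#' @param n_genes number of genes (TSS evenly spaced, alternating strand).
#' @param n_outgroups number of trait-complete outgroup species.
#' @param clade_sizes named integer vector: sizes of the screened
#'   trait-reduced target clades.
#' @param background_sub_rate,conserved_sub_rate per-base substitution
#'   probabilities outside / inside planted conserved regions.
#' @param n_condels number of planted conserved-sequence deletions.
#' @param condel_length_range min/max planted deletion length (bp).
#' @param element_margin conserved flank planted around each deletion (bp).
#' @param n_neutral_elements,element_length_range additional planted
#'   conserved elements without any deletion.
#' @param indel_rate per-base probability of starting a small background
#'   indel (0 = noise-free default); `indel_length_range` its size range.
#' @param outgroup_violations integer vector: for each named/indexed
#'   planted deletion, the number of outgroups that also carry it
#'   (genotype-phenotype violations), e.g. `c("3" = 2)` plants locus 3's
#'   deletion in two outgroups.
#' @param ngap_confound integer vector of planted-deletion indices whose
#'   target-genome junctions get an adjacent assembly N-run (to exercise
#'   the assembly-gap exclusion rule); `ngap_length` its length.
#' @param ... overrides.
#' @return named list of class `simulation_config`.
#' @export
simulation_config <- function(ref_length = 100000, n_genes = 8,
                              n_outgroups = 17,
                              clade_sizes = c(cladeA = 4, cladeB = 3),
                              background_sub_rate = 0.02,
                              conserved_sub_rate = 0.001,
                              n_condels = 20,
                              condel_length_range = c(60, 300),
                              element_margin = 100,
                              n_neutral_elements = 10,
                              element_length_range = c(200, 500),
                              indel_rate = 0,
                              indel_length_range = c(1, 10),
                              outgroup_violations = integer(),
                              ngap_confound = integer(),
                              ngap_length = 100, ...) {
  cfg <- c(as.list(environment()), list(...))
  stopifnot(cfg$background_sub_rate >= 0, cfg$background_sub_rate < 1,
            cfg$conserved_sub_rate >= 0, cfg$conserved_sub_rate < 1,
            cfg$n_condels >= 1, cfg$ref_length >= 10000,
            length(cfg$clade_sizes) >= 2)
  class(cfg) <- "simulation_config"
  cfg
}

# deterministic feature layout: deletions and neutral elements on an even
# grid; errors if anything overlaps (cannot happen on the default grid)
.plan_features <- function(cfg) {
  n_feat <- cfg$n_condels + cfg$n_neutral_elements
  centers <- round(cfg$ref_length * seq_len(n_feat) / (n_feat + 1))
  is_neutral <- rep(FALSE, n_feat)
  if (cfg$n_neutral_elements > 0)
    is_neutral[round(seq(2, n_feat - 1,
                         length.out = cfg$n_neutral_elements))] <- TRUE
  cond_centers <- centers[!is_neutral][seq_len(cfg$n_condels)]
  cond_len <- round(seq(cfg$condel_length_range[1], cfg$condel_length_range[2],
                        length.out = cfg$n_condels))
  condels <- data.frame(
    locus = paste0("condel", sprintf("%02d", seq_len(cfg$n_condels))),
    chrom = "chr1",
    start = cond_centers - floor(cond_len / 2),
    end = cond_centers - floor(cond_len / 2) + cond_len,
    stringsAsFactors = FALSE)
  neut_centers <- centers[is_neutral]
  neut_len <- round(seq(cfg$element_length_range[1], cfg$element_length_range[2],
                        length.out = cfg$n_neutral_elements))
  neutral <- if (cfg$n_neutral_elements > 0)
    data.frame(chrom = "chr1", start = neut_centers - floor(neut_len / 2),
               end = neut_centers - floor(neut_len / 2) + neut_len,
               stringsAsFactors = FALSE)
  else genomic_intervals()
  # conserved regions: each deletion +/- margin, plus the neutral elements
  conserved <- rbind(
    data.frame(chrom = "chr1", start = condels$start - cfg$element_margin,
               end = condels$end + cfg$element_margin),
    neutral[c("chrom", "start", "end")])
  ord <- order(c(condels$start, neutral$start))
  all_start <- c(condels$start, neutral$start)[ord]
  all_end <- c(condels$end, neutral$end)[ord]
  if (any(all_start[-1] - utils::head(all_end, -1) < 2 * cfg$element_margin))
    stop("planted features overlap; reduce feature count or lengths")
  list(condels = condels, conserved = merge_intervals(conserved, 0))
}

.rand_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# substitute each listed position to a different random base
.apply_subs <- function(basev, pos) {
  if (length(pos) == 0) return(basev)
  cur <- basev[pos]
  alt <- vapply(cur, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  basev[pos] <- alt
  basev
}

# assemble one species' genome and chain from its edit list
# dels: df(start, end) ref intervals removed (dq = 0)
# inss: df(pos, len) query insertions at ref position pos (dt = 0)
.build_species <- function(refv, subs_pos, dels, inss, species,
                           ngap_at = numeric(), ngap_length = 100) {
  qv <- .apply_subs(refv, subs_pos)
  ev <- rbind(
    if (nrow(dels)) data.frame(start = dels$start, end = dels$end, qlen = 0)
    else NULL,
    if (nrow(inss)) data.frame(start = inss$pos, end = inss$pos,
                               qlen = inss$len) else NULL)
  L <- length(refv)
  if (is.null(ev)) ev <- data.frame(start = numeric(), end = numeric(),
                                    qlen = numeric())
  ev <- ev[order(ev$start), , drop = FALSE]
  if (nrow(ev) > 1 && any(ev$start[-1] <= utils::head(ev$end, -1)))
    stop("overlapping/adjacent edit events for species ", species)
  if (nrow(ev) && (ev$start[1] <= 0 || ev$end[nrow(ev)] >= L))
    stop("edit event touches chromosome end for species ", species)
  segs <- character(0)
  sizes <- numeric(0); dts <- numeric(0); dqs <- numeric(0)
  prev <- 0
  qlen <- 0
  junction_q <- numeric(0)   # query offsets of deletion junctions
  for (i in seq_len(nrow(ev))) {
    seg <- paste(qv[(prev + 1):ev$start[i]], collapse = "")
    segs <- c(segs, seg)
    qlen <- qlen + nchar(seg)
    sizes <- c(sizes, ev$start[i] - prev)
    dts <- c(dts, ev$end[i] - ev$start[i])
    dqs <- c(dqs, ev$qlen[i])
    if (ev$end[i] > ev$start[i]) junction_q <- c(junction_q, qlen)
    if (ev$qlen[i] > 0) {
      ins <- paste(.rand_bases(ev$qlen[i]), collapse = "")
      segs <- c(segs, ins)
      qlen <- qlen + ev$qlen[i]
    }
    prev <- ev$end[i]
  }
  segs <- c(segs, paste(qv[(prev + 1):L], collapse = ""))
  sizes <- c(sizes, L - prev)
  qseq <- paste(segs, collapse = "")
  # plant assembly N-runs just downstream of flagged deletion junctions
  if (length(ngap_at)) {
    del_q <- junction_q[ngap_at]
    for (q0 in del_q) {
      from <- q0 + 10
      substr(qseq, from + 1, from + ngap_length) <-
        paste(rep("N", ngap_length), collapse = "")
    }
  }
  blocks <- data.frame(size = sizes, dt = c(dts, NA), dq = c(dqs, NA))
  chain <- alignment_chain(score = sum(sizes), ref_name = "chr1",
                           ref_size = L, ref_start = 0, ref_end = L,
                           query_name = "chr1", query_size = nchar(qseq),
                           query_strand = "+", query_start = 0,
                           query_end = nchar(qseq), chain_id = "1",
                           blocks = blocks)
  list(genome = stats::setNames(qseq, "chr1"), chain = chain)
}

#' Simulate a complete synthetic screen bundle
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; the same seed yields an identical bundle.
#' @param dir optional directory; when given, the bundle is also written
#'   to disk (FASTA, chain, gene model TSV, species table, Newick tree,
#'   truth TSV).
#' @return list with `ref_genome`, `genomes`, `chains_by_species`,
#'   `genes`, `species_config`, `tree`, `truth` (planted-deletion truth
#'   table with an `expected_detectable` flag) and `config`.
#' @export
simulate_condel_bundle <- function(config = simulation_config(), seed = 1,
                                   dir = NULL) {
  cfg <- config
  set.seed(seed)
  plan <- .plan_features(cfg)
  condels <- plan$condels
  L <- cfg$ref_length
  refv <- .rand_bases(L)
  ref_genome <- stats::setNames(paste(refv, collapse = ""), "chr1")

  # per-base substitution rate: conserved regions evolve slowly
  rate <- rep(cfg$background_sub_rate, L)
  for (i in seq_len(nrow(plan$conserved)))
    rate[(plan$conserved$start[i] + 1):plan$conserved$end[i]] <-
      cfg$conserved_sub_rate

  outgroups <- sprintf("og%02d", seq_len(cfg$n_outgroups))
  clade_names <- names(cfg$clade_sizes)
  targets <- unlist(lapply(clade_names, function(cl)
    sprintf("tg%s%d", sub("clade", "", cl), seq_len(cfg$clade_sizes[[cl]]))))
  target_clade <- rep(clade_names, cfg$clade_sizes)
  names(target_clade) <- targets

  # which outgroups carry which planted deletion (violations)
  viol <- integer(nrow(condels))
  if (length(cfg$outgroup_violations)) {
    idx <- as.integer(names(cfg$outgroup_violations))
    if (is.null(names(cfg$outgroup_violations)))
      idx <- seq_along(cfg$outgroup_violations)
    viol[idx] <- as.integer(cfg$outgroup_violations)
  }
  if (any(viol > cfg$n_outgroups)) stop("more violations than outgroups")

  genomes <- list(); chains <- list()
  sample_indels <- function() {
    if (cfg$indel_rate <= 0) return(NULL)
    pos <- which(stats::runif(L) < cfg$indel_rate)
    if (!length(pos)) return(NULL)
    len <- sample(cfg$indel_length_range[1]:cfg$indel_length_range[2],
                  length(pos), replace = TRUE)
    data.frame(pos = pos, len = len, del = stats::runif(length(pos)) < 0.5)
  }
  drop_near_planted <- function(idl) {
    if (is.null(idl)) return(NULL)
    near <- vapply(idl$pos, function(p)
      any(p >= condels$start - 500 & p <= condels$end + 500), logical(1))
    idl <- idl[!near & idl$pos > 100 & idl$pos < L - 100, , drop = FALSE]
    if (nrow(idl) == 0) NULL else idl
  }
  for (si in seq_along(outgroups)) {
    sp <- outgroups[si]
    subs <- which(stats::runif(L) < rate)
    dels <- condels[viol >= si, c("start", "end"), drop = FALSE]
    idl <- drop_near_planted(sample_indels())
    extra_dels <- if (!is.null(idl) && any(idl$del))
      data.frame(start = idl$pos[idl$del], end = idl$pos[idl$del] + idl$len[idl$del])
    else NULL
    inss <- if (!is.null(idl) && any(!idl$del))
      data.frame(pos = idl$pos[!idl$del], len = idl$len[!idl$del])
    else data.frame(pos = numeric(), len = numeric())
    all_dels <- rbind(dels, extra_dels)
    b <- .build_species(refv, subs, all_dels, inss, sp)
    genomes[[sp]] <- b$genome; chains[[sp]] <- list(b$chain)
  }
  for (sp in targets) {
    cl <- target_clade[[sp]]
    subs <- which(stats::runif(L) < rate)
    dels <- condels[, c("start", "end")]
    idl <- drop_near_planted(sample_indels())
    extra_dels <- if (!is.null(idl) && any(idl$del))
      data.frame(start = idl$pos[idl$del], end = idl$pos[idl$del] + idl$len[idl$del])
    else NULL
    inss <- if (!is.null(idl) && any(!idl$del))
      data.frame(pos = idl$pos[!idl$del], len = idl$len[!idl$del])
    else data.frame(pos = numeric(), len = numeric())
    ngap_at <- which(seq_len(nrow(condels)) %in% cfg$ngap_confound)
    all_dels <- rbind(dels, extra_dels)
    ord <- order(all_dels$start)
    all_dels <- all_dels[ord, , drop = FALSE]
    # indices of confounded planted deletions among this species' deletions
    ngap_idx <- which(all_dels$start %in% condels$start[ngap_at])
    b <- .build_species(refv, subs, all_dels, inss, sp,
                        ngap_at = ngap_idx, ngap_length = cfg$ngap_length)
    genomes[[sp]] <- b$genome; chains[[sp]] <- list(b$chain)
  }

  # genes: evenly spaced TSS, alternating strand, two exons each
  genes <- list()
  for (i in seq_len(cfg$n_genes)) {
    tss <- round(L * i / (cfg$n_genes + 1))
    strand <- if (i %% 2 == 1) "+" else "-"
    span <- 2000
    tx <- if (strand == "+") c(tss, tss + span) else c(tss - span + 1, tss + 1)
    gid <- sprintf("gene%02d", i)
    genes[[gid]] <- gene_model(
      gid, "chr1", strand,
      list(list(tx_id = paste0(gid, ".t1"), tx_start = tx[1], tx_end = tx[2],
                exons = genomic_intervals(
                  chrom = "chr1",
                  start = c(tx[1], tx[2] - 400), end = c(tx[1] + 400, tx[2])))))
  }

  species_config <- data.frame(
    species = c("ref", outgroups, targets),
    role = c("reference", rep("outgroup", length(outgroups)),
             rep("target", length(targets))),
    clade = c("reference", rep("outgroup", length(outgroups)),
              unname(target_clade)),
    screened = c(FALSE, rep(FALSE, length(outgroups)),
                 rep(TRUE, length(targets))),
    stringsAsFactors = FALSE)

  nwk <- paste0("(ref:1.0,", paste(sprintf("%s:1.0", outgroups), collapse = ","),
                ",(", paste(sprintf("%s:0.3", targets[target_clade == clade_names[1]]),
                            collapse = ","), "):0.7",
                ",(", paste(sprintf("%s:0.3", targets[target_clade == clade_names[2]]),
                            collapse = ","), "):0.7);")
  tree <- ape::read.tree(text = nwk)

  truth <- data.frame(
    locus = condels$locus, chrom = condels$chrom,
    start = condels$start, end = condels$end,
    length = condels$end - condels$start,
    clades = paste(clade_names, collapse = ","),
    n_outgroup_violations = viol,
    ngap_confound = seq_len(nrow(condels)) %in% cfg$ngap_confound,
    stringsAsFactors = FALSE)
  truth$expected_detectable <- truth$length >= 50 &
    truth$n_outgroup_violations <= 1 & !truth$ngap_confound

  bundle <- list(ref_genome = ref_genome, genomes = genomes,
                 chains_by_species = chains, genes = genes,
                 species_config = species_config, tree = tree,
                 truth = truth, config = cfg)
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

#' Write a synthetic bundle to disk
#' @param bundle list from [simulate_condel_bundle()].
#' @param dir output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome(bundle$ref_genome, file.path(dir, "reference.fa"))
  for (sp in names(bundle$genomes)) {
    write_genome(bundle$genomes[[sp]], file.path(dir, paste0(sp, ".fa")))
    write_chain(bundle$chains_by_species[[sp]],
                file.path(dir, paste0(sp, ".chain")))
  }
  write_gene_models(bundle$genes, file.path(dir, "genes.tsv"))
  sc <- bundle$species_config
  sc$genome_fasta <- ifelse(sc$role == "reference", "reference.fa",
                            paste0(sc$species, ".fa"))
  sc$chain_file <- ifelse(sc$role == "reference", NA,
                          paste0(sc$species, ".chain"))
  utils::write.table(sc, file.path(dir, "species.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a bundle written by [write_bundle()]
#' @param dir bundle directory.
#' @return in-memory bundle list (without the simulation config).
#' @export
read_bundle <- function(dir) {
  sc <- utils::read.table(file.path(dir, "species.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  ref_genome <- read_genome(file.path(dir, sc$genome_fasta[sc$role == "reference"]))
  genomes <- list(); chains <- list()
  for (i in which(sc$role != "reference")) {
    sp <- sc$species[i]
    genomes[[sp]] <- read_genome(file.path(dir, sc$genome_fasta[i]))
    chains[[sp]] <- read_chain(file.path(dir, sc$chain_file[i]))
  }
  truth_path <- file.path(dir, "truth.tsv")
  list(ref_genome = ref_genome, genomes = genomes,
       chains_by_species = chains,
       genes = read_gene_models(file.path(dir, "genes.tsv")),
       species_config = sc,
       tree = if (file.exists(file.path(dir, "tree.nwk")))
         ape::read.tree(file.path(dir, "tree.nwk")) else NULL,
       truth = if (file.exists(truth_path))
         utils::read.table(truth_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE) else NULL)
}

#' Precision and recall of candidates against the planted truth
#'
#' A truth locus is recovered when some candidate lies within `slop` bp of
#' it (overlap after expanding the locus by `slop`); a candidate is a true
#' positive under the same rule.
#'
#' @param candidates interval data frame (`chrom`, `start`, `end`).
#' @param truth_table truth data frame from [simulate_condel_bundle()].
#' @param slop tolerance in bp.
#' @return list `precision`, `recall`, `report` (per-locus match table).
#' @export
evaluate_recovery <- function(candidates, truth_table, slop = 0) {
  exp_truth <- truth_table
  exp_truth$start <- pmax(0, exp_truth$start - slop)
  exp_truth$end <- exp_truth$end + slop
  recovered <- if (nrow(candidates))
    overlaps_any(exp_truth[c("chrom", "start", "end")],
                 candidates[c("chrom", "start", "end")])
  else rep(FALSE, nrow(exp_truth))
  tp <- if (nrow(candidates))
    overlaps_any(candidates[c("chrom", "start", "end")],
                 exp_truth[c("chrom", "start", "end")])
  else logical(0)
  report <- data.frame(locus = truth_table$locus, recovered = recovered,
                       stringsAsFactors = FALSE)
  list(precision = if (nrow(candidates)) mean(tp) else NA_real_,
       recall = mean(recovered), report = report)
}
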