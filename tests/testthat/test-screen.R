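plus_gene <- function(tss, id = "g", chrom = "chr1") {
  gene_model(id, chrom, "+",
             list(list(tx_id = paste0(id, ".t1"), tx_start = tss,
                       tx_end = tss + 1000,
                       exons = genomic_intervals(chrom = chrom, start = tss,
                                                 end = tss + 1000))))
}

test_that("scan window spans 200 kb each side of the TSS (400,001 bp)", {
  g <- plus_gene(500000)
  w <- gene_scan_window(g, flank = 200000, chrom_length = 2e6)
  expect_equal(w$start, 300000)
  expect_equal(w$end, 700001)
  expect_equal(w$end - w$start, 400001)
})

test_that("minus-strand windows centre on tx_end - 1 and clip at edges", {
  gm <- gene_model("gm", "chr1", "-",
                   list(list(tx_id = "t", tx_start = 200, tx_end = 1000,
                             exons = genomic_intervals(chrom = "chr1",
                                                       start = 200, end = 1000))))
  w <- gene_scan_window(gm, flank = 500, chrom_length = 1e6)
  expect_equal((w$start + w$end - 1) / 2, 999)  # centred on TSS = 999
  gclip <- plus_gene(100)
  wc <- gene_scan_window(gclip, flank = 200000, chrom_length = 1e6)
  expect_equal(wc$start, 0)
  expect_equal(wc$end, 200101)
  expect_error(gene_scan_window(plus_gene(5000), chrom_length = 2000),
               "outside")
})

test_that("scorable genes require confident mappings in both roles", {
  sc <- data.frame(
    species = c(paste0("og", 1:17), paste0("tg", 1:5)),
    role = c(rep("outgroup", 17), rep("target", 5)),
    clade = c(rep("outgroup", 17), rep("cladeA", 5)),
    screened = c(rep(FALSE, 17), rep(TRUE, 5)))
  mk_calls <- function(n_og, n_tg, gene = "g1") {
    data.frame(gene_id = gene,
               species = c(paste0("og", seq_len(n_og)),
                           paste0("tg", seq_len(n_tg))),
               confidence = "confident")
  }
  expect_equal(scorable_genes(mk_calls(17, 5), sc), "g1")
  expect_equal(length(scorable_genes(mk_calls(16, 5), sc)), 0)
  expect_equal(length(scorable_genes(mk_calls(17, 4), sc)), 0)
  # counting oracle on random call tables
  set.seed(31)
  for (rep in 1:10) {
    calls <- data.frame(
      gene_id = "gX",
      species = sample(sc$species, 15),
      confidence = sample(c("confident", "ambiguous"), 15, TRUE))
    got <- scorable_genes(calls, sc, min_outgroups = 5, min_targets = 2)
    conf <- calls[calls$confidence == "confident", ]
    roles <- sc$role[match(conf$species, sc$species)]
    keep <- sum(roles == "outgroup") >= 5 && sum(roles == "target") >= 2
    expect_equal(length(got) == 1, keep)
  }
})

test_that("clade consensus uses ceil(frac * size) in every screened clade", {
  win <- list(chrom = "chr1", start = 0, end = 10000)
  clades <- list(A = paste0("a", 1:4), B = paste0("b", 1:3))
  # thresholds: ceil(8/3) = 3 of 4 in A, ceil(2) = 2 of 3 in B
  tracks <- c(
    lapply(1:4, function(i) genomic_intervals(chrom = "chr1", start = 1000,
                                              end = 1200)),
    lapply(1:3, function(i) genomic_intervals(chrom = "chr1", start = 1000,
                                              end = 1200)))
  names(tracks) <- c(paste0("a", 1:4), paste0("b", 1:3))
  got <- target_deletion_consensus(win, tracks, clades)
  expect_equal(got$start, 1000)
  expect_equal(got$end, 1200)
  # drop to 2 of 4 in clade A: consensus fails there, conjunction empty
  tracks2 <- tracks
  tracks2[["a1"]] <- genomic_intervals()
  tracks2[["a2"]] <- genomic_intervals()
  expect_equal(nrow(target_deletion_consensus(win, tracks2, clades)), 0)
  # one clade satisfied, other not: excluded (conjunction over clades)
  tracks3 <- tracks
  for (s in paste0("b", 1:3)) tracks3[[s]] <- genomic_intervals()
  expect_equal(nrow(target_deletion_consensus(win, tracks3, clades)), 0)
  expect_error(target_deletion_consensus(win, tracks, list(A = character())),
               "no species")
})

test_that("clade consensus matches a per-base counting oracle", {
  set.seed(37)
  win <- list(chrom = "toy", start = 0, end = 100000)
  clades <- list(A = paste0("a", 1:4), B = paste0("b", 1:3))
  for (rep in 1:4) {
    tracks <- random_tracks(7, 25, 100000, seed = 100 + rep)
    names(tracks) <- c(paste0("a", 1:4), paste0("b", 1:3))
    got <- target_deletion_consensus(win, tracks, clades)
    okA <- oracle_coverage_count(tracks[1:4], 3, 1, 100000)
    okB <- oracle_coverage_count(tracks[5:7], 2, 1, 100000)
    exp <- oracle_intersect(okA, okB, 100000)
    expect_equal(as.data.frame(got), as.data.frame(exp), ignore_attr = TRUE)
  }
})

test_that("raw/final size filters and merging behave as specified", {
  win <- list(chrom = "chr1", start = 0, end = 10000)
  # consensus [0,100) meets conserved [30,55): 25 bp raw, below final 50
  res <- call_condels(win,
                      genomic_intervals(chrom = "chr1", start = 0, end = 100),
                      genomic_intervals(chrom = "chr1", start = 30, end = 55))
  expect_equal(res$raw$start, 30)
  expect_equal(res$raw$end, 55)
  expect_equal(nrow(res$final), 0)
  # two raw pieces 15 bp apart merge into one final candidate
  res2 <- call_condels(win,
                       genomic_intervals(chrom = "chr1", start = 0, end = 100),
                       genomic_intervals(chrom = "chr1", start = c(0, 55),
                                         end = c(40, 100)))
  expect_equal(res2$final$start, 0)
  expect_equal(res2$final$end, 100)
  # pieces under min_raw vanish before merging
  res3 <- call_condels(win,
                       genomic_intervals(chrom = "chr1", start = 0, end = 200),
                       genomic_intervals(chrom = "chr1", start = c(0, 30),
                                         end = c(10, 90)))
  expect_equal(res3$raw$start, 30)
})

test_that("candidate calling matches per-base set algebra on random tracks", {
  set.seed(41)
  win <- list(chrom = "toy", start = 0, end = 50000)
  for (rep in 1:5) {
    cons <- random_tracks(1, 30, 50000, seed = 200 + rep)[[1]]
    cov <- random_tracks(1, 30, 50000, seed = 300 + rep)[[1]]
    res <- call_condels(win, cons, cov, merge_dist = 20, min_raw = 5,
                        min_final = 25)
    inter <- oracle_intersect(merge_intervals(cons, 0),
                              merge_intervals(cov, 0), 50000)
    raw <- inter[inter$end - inter$start >= 5, ]
    merged <- merge_intervals(raw, 20)
    final <- merged[merged$end - merged$start >= 25, ]
    expect_equal(as.data.frame(res$final), as.data.frame(final),
                 ignore_attr = TRUE)
  }
})

test_that("violation filter counts only scorable outgroups", {
  cand <- genomic_intervals(chrom = "chr1", start = 1000, end = 1100)
  spans <- list(og1 = list(chrom = "chr1", start = 0, end = 50000),
                og2 = list(chrom = "chr1", start = 0, end = 50000),
                og3 = list(chrom = "chr1", start = 2000, end = 50000))
  gap_at <- genomic_intervals(chrom = "chr1", start = 1050, end = 1060)
  none <- genomic_intervals()
  # 0 violations: kept
  k0 <- outgroup_violation_filter(cand, list(og1 = none, og2 = none,
                                             og3 = none), spans)
  expect_equal(nrow(k0), 1)
  expect_equal(k0$violations, 0L)
  # 2 violations: dropped
  k2 <- outgroup_violation_filter(cand, list(og1 = gap_at, og2 = gap_at,
                                             og3 = none), spans)
  expect_equal(nrow(k2), 0)
  # og3's chain does not span the candidate, so its gap cannot count
  k1 <- outgroup_violation_filter(cand, list(og1 = gap_at, og2 = none,
                                             og3 = gap_at), spans)
  expect_equal(k1$violations, 1L)
  expect_equal(nrow(k1), 1)
})

test_that("deduplication collapses exact intervals and unions gene links", {
  cands <- data.frame(chrom = "chr1", start = c(100, 100, 500),
                      end = c(200, 200, 600),
                      gene_id = c("gA", "gB", "gA"))
  dd <- deduplicate_condels(cands)
  expect_equal(nrow(dd), 2)
  expect_equal(dd$linked_genes[dd$start == 100], "gA,gB")
  expect_equal(dd$n_linked_genes[dd$start == 100], 2)
  # overlapping but unequal intervals are kept distinct
  cands2 <- data.frame(chrom = "chr1", start = c(100, 120),
                       end = c(200, 220), gene_id = c("gA", "gB"))
  expect_equal(nrow(deduplicate_condels(cands2)), 2)
})

test_that("screen output is invariant under species input order", {
  b <- default_bundle()
  res1 <- default_screen()
  b2 <- b
  perm <- rev(seq_along(b$genomes))
  b2$genomes <- b$genomes[perm]
  b2$chains_by_species <- b$chains_by_species[perm]
  res2 <- condel_screen(b2)
  expect_equal(as.data.frame(res2$candidates), as.data.frame(res1$candidates))
})

test_that("every final candidate lies inside a linked gene's scan window", {
  res <- default_screen()
  b <- default_bundle()
  cands <- res$candidates
  for (i in seq_len(nrow(cands))) {
    genes <- strsplit(cands$linked_genes[i], ",")[[1]]
    inside <- vapply(genes, function(g) {
      w <- gene_scan_window(b$genes[[g]], flank = res$config$flank,
                            chrom_length = nchar(b$ref_genome[[cands$chrom[i]]]))
      w$start <= cands$start[i] && w$end >= cands$end[i]
    }, logical(1))
    expect_true(all(inside))
  }
})
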