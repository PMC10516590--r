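gap_chain <- function(blocks, ref_start = 100, query_start = 200,
                      strand = "+", qsize = 900) {
  n <- nrow(blocks)
  ref_span <- sum(blocks$size) + sum(blocks$dt[-n])
  q_span <- sum(blocks$size) + sum(blocks$dq[-n])
  alignment_chain(50, "refChr1", 100000, ref_start, ref_start + ref_span,
                  "qChr1", qsize, strand, query_start, query_start + q_span,
                  "7", blocks)
}

test_that("gap extraction classifies single- and double-sided junctions", {
  single <- gap_chain(data.frame(size = c(10, 13), dt = c(5, NA),
                                 dq = c(0, NA)))
  g <- extract_chain_gaps(single, species = "sp")
  expect_equal(nrow(g), 1)
  expect_equal(c(g$start, g$end), c(110, 115))
  expect_equal(g$sided, "single")
  expect_equal(g$query_start, g$query_end)

  dbl <- gap_chain(data.frame(size = c(10, 13), dt = c(5, NA), dq = c(3, NA)))
  g2 <- extract_chain_gaps(dbl)
  expect_equal(g2$sided, "double")
  expect_equal(g2$query_end - g2$query_start, 3)

  ins <- gap_chain(data.frame(size = c(10, 13), dt = c(0, NA), dq = c(4, NA)))
  expect_equal(nrow(extract_chain_gaps(ins)), 0)
})

test_that("blocks and gaps tile the chain's reference span disjointly", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(2:8, 1)
    blocks <- data.frame(size = sample.int(50, n),
                         dt = c(sample(0:30, n - 1, TRUE), NA),
                         dq = c(sample(0:30, n - 1, TRUE), NA))
    ch <- gap_chain(blocks)
    both <- rbind(chain_block_ref_intervals(ch)[c("chrom", "start", "end")],
                  extract_chain_gaps(ch)[c("chrom", "start", "end")])
    both <- both[order(both$start), ]
    expect_equal(both$start[1], ch$ref_start)
    expect_equal(both$end[nrow(both)], ch$ref_end)
    if (nrow(both) > 1)
      expect_true(all(both$start[-1] == both$end[-nrow(both)]))
  }
})

test_that("minus-strand query context converts to forward coordinates", {
  ch <- gap_chain(data.frame(size = c(10, 13), dt = c(5, NA), dq = c(3, NA)),
                  strand = "-", qsize = 900)
  g <- extract_chain_gaps(ch)
  # strand-local gap occupies [210, 213); forward = [900-213, 900-210)
  expect_equal(c(g$query_start, g$query_end), c(687, 690))
})

test_that("gaps near assembly N-runs are invalidated, others kept", {
  # query genome with a 10-N run at [260, 270)
  q <- paste0(strrep("A", 260), strrep("N", 10), strrep("G", 630))
  genome <- c(qChr1 = q)
  near <- gap_chain(data.frame(size = c(10, 13), dt = c(5, NA), dq = c(0, NA)),
                    query_start = 200)   # junction at query 210, 50 bp away
  g <- filter_gaps_near_assembly_gaps(extract_chain_gaps(near), genome)
  expect_false(g$valid)
  far <- gap_chain(data.frame(size = c(10, 13), dt = c(5, NA), dq = c(3, NA)),
                   query_start = 420)    # context [430,433), 150+ bp away
  g2 <- filter_gaps_near_assembly_gaps(extract_chain_gaps(far), genome)
  expect_true(g2$valid)
  expect_error(
    filter_gaps_near_assembly_gaps(extract_chain_gaps(far),
                                   c(other = "ACGT")),
    "absent")
})

test_that("validity flags match a brute-force distance oracle", {
  set.seed(9)
  for (rep in 1:8) {
    qlen <- 10000
    qv <- rep("A", qlen)
    nstart <- sort(sample.int(qlen - 60, 4))
    for (s in nstart) qv[(s + 1):(s + sample(6:20, 1))] <- "N"
    q <- paste(qv, collapse = "")
    genome <- c(qChr1 = q)
    blocks <- data.frame(size = rep(50, 6),
                         dt = c(sample(1:30, 5, TRUE), NA),
                         dq = c(sample(0:30, 5, TRUE), NA))
    ch <- gap_chain(blocks, query_start = sample.int(5000, 1), qsize = 10000)
    gaps <- extract_chain_gaps(ch)
    flagged <- filter_gaps_near_assembly_gaps(gaps, genome,
                                              flank = 100, n_run_min = 6)
    runs <- find_n_runs(q, 6)
    for (i in seq_len(nrow(gaps))) {
      a <- gaps$query_start[i]; b <- gaps$query_end[i]
      d <- min(pmax(0, pmax(runs$start - b, a - runs$end)))
      expect_equal(flagged$valid[i], d > 100)
    }
  }
})

test_that("invalidation is monotone in flank and antitone in run threshold", {
  q <- paste0(strrep("A", 300), strrep("N", 8), strrep("G", 692))
  genome <- c(qChr1 = q)
  ch <- gap_chain(data.frame(size = c(10, 13), dt = c(5, NA), dq = c(0, NA)),
                  query_start = 150)
  gaps <- extract_chain_gaps(ch)
  valid_at <- function(flank, nmin)
    filter_gaps_near_assembly_gaps(gaps, genome, flank, nmin)$valid
  expect_true(valid_at(100, 6))    # junction 160, run at 300: 140 bp away
  expect_false(valid_at(150, 6))   # larger flank can only invalidate more
  expect_true(valid_at(150, 9))    # stricter run length can only validate
})

test_that("merged gap tracks stay within each chain", {
  ch1 <- gap_chain(data.frame(size = c(10, 10, 10), dt = c(5, 15, NA),
                              dq = c(0, 0, NA)))
  gaps <- rbind(extract_chain_gaps(ch1, species = "s1"),
                extract_chain_gaps(ch1, species = "s2"))
  gaps$chain_id[gaps$species == "s2"] <- "other"
  m <- merged_gap_track(gaps, max_dist = 20)
  # within a chain the two gaps (10 bp apart) merge; across chains never
  expect_equal(nrow(m[m$species == "s1", ]), 1)
  expect_equal(nrow(m[m$species == "s2", ]), 1)
  expect_equal(m$start[m$species == "s1"], 110)
  expect_equal(m$end[m$species == "s1"], 140)
  # delegation identity with merge_intervals
  direct <- merge_intervals(
    extract_chain_gaps(ch1)[c("chrom", "start", "end")], 20)
  expect_equal(m[m$species == "s1", c("start", "end")],
               as.data.frame(direct[c("start", "end")]))
})
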