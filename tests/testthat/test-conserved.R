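ident_chain <- function(ref_len = 200, ref_start = 0, blocks = NULL) {
  if (is.null(blocks))
    blocks <- data.frame(size = ref_len, dt = NA, dq = NA)
  n <- nrow(blocks)
  span <- sum(blocks$size) + sum(blocks$dt[-n])
  qspan <- sum(blocks$size) + sum(blocks$dq[-n])
  alignment_chain(10, "chr1", 100000, ref_start, ref_start + span,
                  "chr1", 100000, "+", ref_start, ref_start + qspan,
                  "1", blocks)
}

test_that("window identity is exact on constructed blocks", {
  ref <- c(chr1 = strrep("ACGTTGCAAC", 10))   # 100 bp
  ch <- ident_chain(10)
  # identical sequences: one window, identity 1
  w <- score_windows(ch, ref, ref, window_sizes = 10)
  expect_equal(nrow(w), 1)
  expect_equal(w$identity, 1.0)
  # one mismatch in a 10 bp block: identity 0.9
  q <- ref
  substr(q[["chr1"]], 5, 5) <- ifelse(substr(ref[["chr1"]], 5, 5) == "A",
                                      "C", "A")
  names(q) <- "chr1"
  w2 <- score_windows(ch, ref, q, window_sizes = 10)
  expect_equal(w2$identity, 0.9)
  # 12 bp block, w = 10: three windows at offsets 0, 1, 2
  ch12 <- ident_chain(12)
  w3 <- score_windows(ch12, ref, ref, window_sizes = 10)
  expect_equal(w3$start, c(0, 1, 2))
  expect_equal(w3$end, c(10, 11, 12))
})

test_that("identity is case-insensitive and N never matches", {
  ref <- c(chr1 = "ACGTACGTAC")
  soft <- c(chr1 = "acgtacgtac")
  ch <- ident_chain(10)
  expect_equal(score_windows(ch, ref, soft, window_sizes = 10)$identity, 1)
  nn <- c(chr1 = "ACGTNNGTAC")
  expect_equal(score_windows(ch, ref, nn, window_sizes = 10)$identity, 0.8)
})

test_that("windows never span inter-block gaps", {
  ref <- c(chr1 = strrep("A", 200))
  ch <- ident_chain(blocks = data.frame(size = c(12, 15), dt = c(8, NA),
                                        dq = c(0, NA)))
  w <- score_windows(ch, ref, ref, window_sizes = 10)
  # block 1 spans [0,12): windows start 0..2; block 2 spans [20,35): 20..25
  expect_true(all(w$end <= 12 | w$start >= 20))
  expect_equal(sum(w$start < 12), 3)
  expect_equal(sum(w$start >= 20), 6)
})

test_that("quota selection keeps the minimal top set plus ties", {
  # toy genome 1000 bp, quota 5% = 50 bp; well-separated 10 bp windows
  # with distinct scores: exactly the top 5 selected
  win <- data.frame(species = "s", chain_id = "1", chrom = "chr1",
                    start = seq(0, 190, 20), end = seq(10, 200, 20),
                    window_size = 10,
                    identity = seq(1, 0.1, length.out = 10))
  el <- call_conserved_elements(win, genome_length = 1000,
                                coverage_frac = 0.05, merge_dist = 0)
  expect_equal(sum(el$end - el$start), 50)
  expect_equal(el$start, seq(0, 80, 20))

  # global tie: everything comes back
  win$identity <- 1
  el2 <- call_conserved_elements(win, 1000, 0.05, merge_dist = 0)
  expect_equal(sum(el2$end - el2$start), 100)

  # under-quota input warns and returns all windows
  expect_warning(
    call_conserved_elements(win[1:2, ], 10000, 0.05, 0), "below quota")
})

test_that("selection matches an accumulate-and-flatten oracle", {
  set.seed(17)
  for (rep in 1:6) {
    n <- 120
    s <- sample.int(9000, n)
    w <- sample(c(10, 25), n, TRUE)
    win <- data.frame(species = "s", chain_id = "1", chrom = "chr1",
                      start = s, end = s + w, window_size = w,
                      identity = sample(seq(0.5, 1, 0.05), n, TRUE))
    quota_frac <- 0.04
    el <- call_conserved_elements(win, 10000, quota_frac, merge_dist = 20)

    # oracle: walk windows sorted by identity, recomputing union length,
    # stop at quota, include the last tie class wholesale
    ord <- order(-win$identity)
    covered <- logical(10000)
    cut <- NA
    for (i in ord) {
      covered[(win$start[i] + 1):win$end[i]] <- TRUE
      if (sum(covered) >= quota_frac * 10000) { cut <- win$identity[i]; break }
    }
    sel <- win[win$identity >= cut, ]
    exp <- merge_intervals(sel[c("chrom", "start", "end")], 20)
    expect_equal(el[c("chrom", "start", "end")],
                 as.data.frame(exp),
                 ignore_attr = TRUE)
  }
})

test_that("selected coverage meets quota and is minimal up to the tie class", {
  set.seed(23)
  n <- 150
  s <- sample.int(9000, n)
  win <- data.frame(species = "s", chain_id = "1", chrom = "chr1",
                    start = s, end = s + 10, window_size = 10,
                    identity = sample(seq(0.6, 1, 0.1), n, TRUE))
  el <- call_conserved_elements(win, 10000, 0.05, merge_dist = 0)
  expect_gte(condelscan:::interval_union_width(el[c("chrom", "start", "end")]),
             0.05 * 10000)
  # the selection cutoff is the lowest identity class whose inclusion
  # reaches quota; dropping that whole class must fall below quota
  classes <- sort(unique(win$identity), decreasing = TRUE)
  cutoff <- NA
  for (cl in classes) {
    sel <- win[win$identity >= cl, ]
    if (condelscan:::interval_union_width(sel[c("chrom", "start", "end")]) >=
        0.05 * 10000) { cutoff <- cl; break }
  }
  above <- win[win$identity > cutoff, ]
  expect_lt(condelscan:::interval_union_width(above[c("chrom", "start", "end")]),
            0.05 * 10000)
  # and the selected elements are exactly the merged >= cutoff windows
  sel <- win[win$identity >= cutoff, ]
  expect_equal(el[c("chrom", "start", "end")],
               as.data.frame(merge_intervals(sel[c("chrom", "start", "end")], 0)),
               ignore_attr = TRUE)
})

test_that("raising the coverage quota never removes an element", {
  set.seed(29)
  n <- 100
  s <- sample.int(9000, n)
  win <- data.frame(species = "s", chain_id = "1", chrom = "chr1",
                    start = s, end = s + 10, window_size = 10,
                    identity = sample(seq(0.6, 1, 0.1), n, TRUE))
  lo <- call_conserved_elements(win, 10000, 0.03, merge_dist = 0)
  hi <- call_conserved_elements(win, 10000, 0.08, merge_dist = 0)
  # every base of every low-quota element remains covered at high quota
  for (i in seq_len(nrow(lo)))
    expect_true(any(hi$start <= lo$start[i] & hi$end >= lo$end[i]))
})
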