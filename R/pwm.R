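#' Log-odds matrix from a position frequency matrix
#'
#' Column frequencies get a pseudocount (split by background) before
#' conversion to log2 odds against the background. Defaults follow a
#' common motif-scanning convention: total pseudocount 0.8 and a uniform
#' 0.25 background.
#'
#' @param pfm a `pfm` from [read_jaspar()], or a bare 4xL matrix with
#'   rownames A, C, G, T.
#' @param pseudocount total pseudocount added per column.
#' @param background length-4 base composition (A, C, G, T), summing to 1.
#' @return object of class `pwm`: list with `id`, `logodds` (4xL), and the
#'   per-column `min`/`max` attainable scores.
#' @export
pwm_from_pfm <- function(pfm, pseudocount = 0.8, background = rep(0.25, 4)) {
  m <- if (inherits(pfm, "pfm")) pfm$matrix else pfm
  stopifnot(nrow(m) == 4, all(rownames(m) == c("A", "C", "G", "T")),
            length(background) == 4, abs(sum(background) - 1) < 1e-8)
  cs <- colSums(m)
  probs <- sweep(m + pseudocount * background, 2, cs + pseudocount, "/")
  lo <- log2(probs / background)
  structure(list(id = if (inherits(pfm, "pfm")) pfm$id else "pwm",
                 logodds = lo,
                 min = apply(lo, 2, min), max = apply(lo, 2, max)),
            class = "pwm")
}

#' Scan a sequence with a position weight matrix
#'
#' Scores every window on both strands and reports those whose *relative*
#' score — the log-odds score rescaled between the matrix's minimum and
#' maximum attainable scores to the range 0..1000 — reaches
#' `min_rel_score`. Windows containing `N` are skipped.
#'
#' @param sequence nucleotide string over `ACGTNacgtn`.
#' @param pwm a `pwm` from [pwm_from_pfm()] (a `pfm` is converted with
#'   defaults).
#' @param min_rel_score minimum relative score (0..1000 scale).
#' @return data frame of hits: `position` (0-based start on the forward
#'   strand), `strand`, `rel_score`.
#' @export
pwm_scan <- function(sequence, pwm, min_rel_score = 925) {
  if (inherits(pwm, "pfm") || (is.matrix(pwm) && nrow(pwm) == 4))
    pwm <- pwm_from_pfm(pwm)
  stopifnot(inherits(pwm, "pwm"))
  L <- ncol(pwm$logodds)
  n <- nchar(sequence)
  empty <- data.frame(position = numeric(), strand = character(),
                      rel_score = numeric(), stringsAsFactors = FALSE)
  if (L > n) return(empty)
  span <- sum(pwm$max) - sum(pwm$min)
  score_strand <- function(seq) {
    idx <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]],
                 c("A", "C", "G", "T"))        # N and friends -> NA
    starts <- seq_len(nchar(seq) - L + 1)
    s <- numeric(length(starts))
    for (k in seq_len(L))
      s <- s + pwm$logodds[cbind(idx[starts + k - 1], k)]
    rel <- (s - sum(pwm$min)) / span * 1000    # NA where a window hit an N
    rel
  }
  fwd <- score_strand(sequence)
  rev <- score_strand(revcomp(sequence))
  hits <- list()
  fi <- which(!is.na(fwd) & fwd >= min_rel_score)
  if (length(fi))
    hits$f <- data.frame(position = fi - 1, strand = "+",
                         rel_score = fwd[fi], stringsAsFactors = FALSE)
  ri <- which(!is.na(rev) & rev >= min_rel_score)
  if (length(ri))
    hits$r <- data.frame(position = n - (ri - 1) - L, strand = "-",
                         rel_score = rev[ri], stringsAsFactors = FALSE)
  out <- if (length(hits)) do.call(rbind, hits) else empty
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
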