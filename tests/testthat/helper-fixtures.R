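# Shared fixtures and independent brute-force oracles. Everything is built
# in code; heavyweight objects are cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default noise-free synthetic bundle and its screen result
default_bundle <- function() cached("bundle", simulate_condel_bundle(seed = 7))
default_screen <- function() cached("screen", condel_screen(default_bundle()))

# a small hand-built chain: two blocks, one single-sided and implicit gaps
toy_chain <- function() {
  parse_chain(paste0(
    "chain 100 refChr1 1000 + 100 128 qChr1 900 + 200 226 1\n",
    "10 5 3\n13\n"))[[1]]
}

# random interval tracks on a toy chromosome
random_tracks <- function(n_species, n_iv, chrom_len, seed) {
  set.seed(seed)
  lapply(seq_len(n_species), function(i) {
    s <- sort(sample.int(chrom_len - 50, n_iv))
    w <- sample(5:40, n_iv, replace = TRUE)
    genomic_intervals(chrom = "toy", start = s, end = pmin(s + w, chrom_len))
  })
}

# per-base counting oracle: bases covered by >= min_species tracks,
# reported as maximal intervals of length >= min_span
oracle_coverage_count <- function(tracks, min_species, min_span, chrom_len) {
  counts <- integer(chrom_len)
  for (t in tracks) {
    cov <- logical(chrom_len)
    for (i in seq_len(nrow(t)))
      if (t$end[i] > t$start[i])
        cov[(t$start[i] + 1):t$end[i]] <- TRUE
    counts <- counts + cov
  }
  hit <- counts >= min_species
  if (!any(hit)) return(genomic_intervals())
  r <- rle(hit)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_span
  if (!any(keep)) return(genomic_intervals())
  genomic_intervals(chrom = tracks[[1]]$chrom[1], start = starts[keep],
                    end = ends[keep])
}

# per-base boolean set algebra for intersections
oracle_intersect <- function(a, b, chrom_len) {
  mk <- function(t) {
    v <- logical(chrom_len)
    for (i in seq_len(nrow(t))) v[(t$start[i] + 1):t$end[i]] <- TRUE
    v
  }
  hit <- mk(a) & mk(b)
  if (!any(hit)) return(genomic_intervals())
  r <- rle(hit)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  genomic_intervals(chrom = a$chrom[1], start = starts[r$values],
                    end = ends[r$values])
}

# independent Boschloo oracle: explicit loops, fisher.test statistics,
# fine nuisance sweep plus local refinement
oracle_boschloo <- function(a, b, c, d, alternative, n_grid = 4001) {
  n1 <- a + b; n2 <- c + d
  fp <- function(x1, x2) {
    m <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2, 2, byrow = TRUE)
    stats::fisher.test(m, alternative = alternative)$p.value
  }
  stat <- fp(a, c)
  sel <- matrix(FALSE, n1 + 1, n2 + 1)
  for (x1 in 0:n1) for (x2 in 0:n2)
    sel[x1 + 1, x2 + 1] <- fp(x1, x2) <= stat * (1 + 1e-13)
  pval <- function(pi) {
    tot <- 0
    for (x1 in 0:n1) for (x2 in 0:n2)
      if (sel[x1 + 1, x2 + 1])
        tot <- tot + stats::dbinom(x1, n1, pi) * stats::dbinom(x2, n2, pi)
    tot
  }
  grid <- seq(1e-6, 1 - 1e-6, length.out = n_grid)
  vals <- rep(0, n_grid)
  for (x1 in 0:n1) for (x2 in 0:n2)
    if (sel[x1 + 1, x2 + 1])
      vals <- vals + stats::dbinom(x1, n1, grid) * stats::dbinom(x2, n2, grid)
  i <- which.max(vals)
  opt <- stats::optimize(pval, c(grid[max(1, i - 1)], grid[min(n_grid, i + 1)]),
                         maximum = TRUE, tol = 1e-12)
  list(stat = stat, p = min(1, max(vals[i], opt$objective)))
}

# patristic distances by explicit path traversal over the edge list
oracle_patristic <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  adj <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  dist_from <- function(s) {
    d <- rep(NA_real_, n_node); d[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1]; w <- adj[[v]][k, 2]
        if (is.na(d[u])) { d[u] <- d[v] + w; queue <- c(queue, u) }
      }
    }
    d[seq_len(n_tip)]
  }
  m <- t(vapply(seq_len(n_tip), dist_from, numeric(n_tip)))
  dimnames(m) <- list(tree$tip.label, tree$tip.label)
  m
}
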