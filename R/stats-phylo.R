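#' Welch's two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] (unequal variances, Satterthwaite
#' degrees of freedom) returning the pieces the screen reports. Two
#' identical constant samples give `t = 0, p = 1`; constant samples with
#' different means have no defined df and raise an error.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @param alternative passed to [stats::t.test()].
#' @return list `t`, `df`, `p.value`.
#' @export
welch_t <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p.value = 1))
    stop("both samples constant with different means: df undefined")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE, alternative = alternative)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Mann-Whitney U test
#'
#' Wrapper around [stats::wilcox.test()]: exact enumeration when the
#' combined sample size is at most 20 and there are no ties, otherwise
#' the normal approximation with tie correction.
#'
#' @param x,y numeric samples.
#' @param alternative passed to [stats::wilcox.test()].
#' @return list `U`, `p.value`, `exact` (whether enumeration was used).
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= 20) && !ties
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = use_exact, correct = TRUE))
  p <- ht$p.value
  # all observations tied: the rank distribution is degenerate
  if (is.na(p)) p <- 1
  list(U = unname(ht$statistic), p.value = p, exact = use_exact)
}

#' Phylogenetic generalized least-squares mean
#'
#' The GLS estimate of a trait's grand mean under Brownian motion on a
#' rooted tree with branch lengths: `(1' V^-1 1)^-1 1' V^-1 y`, where
#' `V[i, j]` is the shared root-to-tip branch length of tips i and j. On a
#' star tree with equal branch lengths this reduces to the arithmetic
#' mean. Tips without values are pruned before estimation, which leaves
#' the estimate unchanged.
#'
#' @param tree an [ape] `phylo` object with branch lengths.
#' @param tip_values named numeric vector (names = tip labels).
#' @return the phylogenetically corrected mean.
#' @export
phylo_mean <- function(tree, tip_values) {
  stopifnot(inherits(tree, "phylo"), !is.null(names(tip_values)))
  missing <- setdiff(names(tip_values), tree$tip.label)
  if (length(missing))
    stop("tip value(s) not in tree: ", paste(missing, collapse = ", "))
  keep <- intersect(tree$tip.label, names(tip_values))
  if (length(keep) < 1) stop("no valued tips in tree")
  if (length(keep) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, keep)
  V <- ape::vcv.phylo(tree)
  y <- tip_values[rownames(V)]
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular phylogenetic covariance (duplicate zero-length tips?)"))
  one <- rep(1, length(y))
  as.numeric((t(one) %*% Vi %*% y) / (t(one) %*% Vi %*% one))
}

#' Patristic distance matrix
#'
#' Tip-to-tip path lengths (sums of branch lengths) for every pair of
#' tips, via [ape::cophenetic.phylo()].
#'
#' @param tree an [ape] `phylo` object with branch lengths.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ape::cophenetic.phylo(tree)
}

#' Welch's t-test on phylogenetically corrected group means
#'
#' A documented recipe for comparing a trait between two groups of
#' species while discounting phylogenetic redundancy: each group's
#' central value is the Brownian-motion GLS mean ([phylo_mean()] on the
#' group's subtree), while the dispersion and degrees of freedom come
#' from the raw per-species values (Welch/Satterthwaite). This mirrors
#' reporting pipelines that feed tree-corrected means into a standard
#' Welch test; it is an interpretation, not a full phylogenetic ANOVA.
#'
#' @param tree an [ape] `phylo` object covering both groups.
#' @param values named numeric vector of per-species trait values.
#' @param group1,group2 character vectors of species names.
#' @return list `t`, `df`, `p.value`, `mean1`, `mean2`.
#' @export
phylo_welch <- function(tree, values, group1, group2) {
  m1 <- phylo_mean(tree, values[group1])
  m2 <- phylo_mean(tree, values[group2])
  x <- values[group1]; y <- values[group2]
  v1 <- stats::var(x) / length(x); v2 <- stats::var(y) / length(y)
  se <- sqrt(v1 + v2)
  tstat <- (m1 - m2) / se
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(t = tstat, df = df, p.value = p, mean1 = m1, mean2 = m2)
}
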