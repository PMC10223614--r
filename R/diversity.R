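# Alpha and beta diversity, implemented from first principles.
#
# Alpha: richness S, Chao1 (S_obs + F1^2/(2 F2), bias-corrected when no
# doubletons), Shannon -sum p ln p, Simpson D = sum p^2, Simpson evenness
# (1/D)/S. Beta: Bray-Curtis BC = 1 - 2 C_ij/(S_i + S_j) on counts, and
# unweighted/weighted (normalized) UniFrac on a phylogeny. Group
# comparisons: Mann-Whitney U (exact null distribution by the standard
# count recursion for small untied samples, otherwise normal approximation
# with tie and continuity corrections) and the variance-ratio F test.

#' Convert relative abundances to pseudo-counts
#'
#' Chao1 needs singleton/doubleton counts, which relative abundances
#' cannot supply; compositional data are converted by multiplying by a
#' documented pseudo-depth and rounding.
#'
#' @param rel relative abundance vector.
#' @param depth pseudo-depth (default 10000).
#' @return integer count vector.
#' @export
to_counts <- function(rel, depth = 10000L) {
  stopifnot(all(rel >= 0))
  as.integer(round(rel / sum(rel) * depth))
}

#' Alpha diversity indices of one sample
#'
#' @param counts non-negative integer count vector (one sample).
#' @return list with \code{richness}, \code{chao1}, \code{shannon},
#'   \code{simpson_D} and \code{evenness} (Simpson evenness
#'   \code{(1/D)/S}).
#' @examples
#' alpha_indices(c(4, 3, 2, 1, 1))$chao1  # 5 + 2^2/(2*1) = 7
#' @export
alpha_indices <- function(counts) {
  if (length(counts) == 0 || all(counts == 0)) {
    stop("sample has no observed taxa", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  obs <- counts[counts > 0]
  S <- length(obs)
  F1 <- sum(obs == 1)
  F2 <- sum(obs == 2)
  chao1 <- if (F2 > 0) S + F1^2 / (2 * F2) else S + F1 * (F1 - 1) / 2
  p <- obs / sum(obs)
  shannon <- -sum(p * log(p))
  simpson_D <- sum(p^2)
  list(richness = S, chao1 = chao1, shannon = shannon,
       simpson_D = simpson_D, evenness = (1 / simpson_D) / S)
}

#' Bray-Curtis dissimilarity
#'
#' \code{BC = 1 - 2 C_ij / (S_i + S_j)} where \code{C_ij} sums, over the
#' species present in both samples, the lesser of the two counts, and
#' \code{S_i}, \code{S_j} are the sample totals. Identical samples give 0,
#' samples with disjoint support give 1.
#'
#' @param i,j count vectors on the same taxon universe.
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(i, j) {
  if (length(i) != length(j)) {
    stop("samples must share the same taxon universe", call. = FALSE)
  }
  Si <- sum(i); Sj <- sum(j)
  if (Si + Sj == 0) stop("both samples are empty", call. = FALSE)
  C <- sum(pmin(i, j))
  1 - 2 * C / (Si + Sj)
}

# abundance mass under each edge of the tree, for a named sample vector
.edge_mass <- function(tree, x) {
  ntip <- length(tree$tip.label)
  vals <- numeric(ntip + tree$Nnode)
  vals[seq_len(ntip)] <- x[tree$tip.label]
  # postorder: children before parents
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    vals[eo[k, 1]] <- vals[eo[k, 1]] + vals[eo[k, 2]]
  }
  vals[tree$edge[, 2]]  # mass below each edge, in tree$edge order
}

#' UniFrac distance between two samples
#'
#' Unweighted: the fraction of observed branch length unique to one
#' sample, \code{sum(b unique) / sum(b observed)}. Weighted (normalized):
#' \code{sum(b |p_i - p_j|) / sum(b (p_i + p_j))} where \code{p} is the
#' fraction of a sample's abundance below each branch. Both lie in
#' [0, 1], are symmetric, and vanish for identical samples.
#'
#' @param i,j named abundance (or count) vectors; names must be leaves of
#'   \code{tree}.
#' @param tree an \code{ape} \code{phylo} with branch lengths.
#' @param weighted logical; weighted (abundance-sensitive) variant.
#' @return distance in [0, 1].
#' @export
unifrac <- function(i, j, tree, weighted = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  for (x in list(i, j)) {
    missing <- setdiff(names(x)[x > 0], tree$tip.label)
    if (length(missing)) {
      stop("taxon not in tree: ", missing[1], call. = FALSE)
    }
  }
  full <- stats::setNames(numeric(length(tree$tip.label)), tree$tip.label)
  xi <- full; xi[names(i)[i > 0]] <- i[i > 0]
  xj <- full; xj[names(j)[j > 0]] <- j[j > 0]
  if (sum(xi) == 0 || sum(xj) == 0) {
    stop("samples must contain at least one taxon present in the tree",
         call. = FALSE)
  }
  b <- tree$edge.length
  mi <- .edge_mass(tree, xi)
  mj <- .edge_mass(tree, xj)
  if (weighted) {
    pi_ <- mi / sum(xi)
    pj_ <- mj / sum(xj)
    denom <- sum(b * (pi_ + pj_))
    if (denom == 0) return(0)
    sum(b * abs(pi_ - pj_)) / denom
  } else {
    presi <- mi > 0
    presj <- mj > 0
    observed <- presi | presj
    unique_b <- xor(presi, presj)
    if (!any(observed)) return(0)
    sum(b[unique_b]) / sum(b[observed])
  }
}

# Exact null distribution of U over 0..mn (no ties). Recursion on the
# largest pooled element: from A it beats all n B values (u - n, m - 1
# left), from B it beats none (u unchanged, n - 1 left).
.u_null_counts <- function(m, n) {
  umax <- m * n
  cnt <- array(0, dim = c(umax + 1, m + 1, n + 1))
  cnt[1, 1, ] <- 1
  cnt[1, , 1] <- 1
  for (i in seq_len(m)) for (j in seq_len(n)) {
    for (u in 0:(i * j)) {
      left <- if (u - j >= 0) cnt[u - j + 1, i, j + 1] else 0
      cnt[u + 1, i + 1, j + 1] <- left + cnt[u + 1, i + 1, j]
    }
  }
  cnt[, m + 1, n + 1]
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent groups. The exact null
#' distribution is used when \code{n_A * n_B <= 400} and the pooled values
#' carry no ties; otherwise the normal approximation with tie and
#' continuity corrections applies.
#'
#' @param groupA,groupB numeric vectors (each non-empty).
#' @return list with \code{U} (statistic of group A), \code{p} (two-sided)
#'   and \code{method}.
#' @export
mann_whitney_u <- function(groupA, groupB) {
  if (!length(groupA) || !length(groupB)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  m <- length(groupA); n <- length(groupB)
  pooled <- c(groupA, groupB)
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(pooled))
  if (m * n <= 400 && !ties) {
    cnt <- .u_null_counts(m, n)
    tot <- sum(cnt)
    lo <- sum(cnt[seq_len(round(U) + 1)]) / tot           # P(U <= u)
    hi <- sum(cnt[(round(U) + 1):length(cnt)]) / tot      # P(U >= u)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- m * n / 2
    tie_tab <- table(pooled)
    N <- m + n
    sigma2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

#' Variance-ratio F test (two-sided)
#'
#' \code{F = s_A^2 / s_B^2} compared against the F distribution with
#' \code{n_A - 1}, \code{n_B - 1} degrees of freedom.
#'
#' @param groupA,groupB numeric vectors, each with at least 2 values and
#'   nonzero variance.
#' @return list with \code{F}, \code{df}, and two-sided \code{p}.
#' @export
f_test_variance <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  vA <- stats::var(groupA); vB <- stats::var(groupB)
  if (vA == 0 || vB == 0) {
    stop("degenerate (zero) variance in a group", call. = FALSE)
  }
  Fstat <- vA / vB
  df <- c(length(groupA) - 1, length(groupB) - 1)
  pl <- stats::pf(Fstat, df[1], df[2])
  p <- min(1, 2 * min(pl, 1 - pl))
  list(F = Fstat, df = df, p = p)
}

#' Per-sample diversity report
#'
#' @param study a \code{paired_study}.
#' @return data frame with sample_id, richness, chao1, shannon,
#'   simpson_D, evenness.
#' @export
diversity_report <- function(study) {
  stopifnot(inherits(study, "paired_study"))
  rows <- lapply(seq_len(nrow(study$counts)), function(k) {
    a <- alpha_indices(study$counts[k, ])
    data.frame(sample_id = rownames(study$counts)[k],
               richness = a$richness, chao1 = a$chao1,
               shannon = a$shannon, simpson_D = a$simpson_D,
               evenness = a$evenness, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
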