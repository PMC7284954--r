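#' Paired t-test
#'
#' Classical paired t statistic computed from scratch on the within-pair
#' differences: \eqn{t = \bar d / (s_d/\sqrt n)} with \eqn{df = n - 1} and a
#' two-sided p-value from the t distribution. Pairs with a missing value on
#' either side are dropped (with a message).
#'
#' @param x,y numeric vectors of equal length (treatment and control, or the
#'   two host lineages measured in parallel).
#' @return list with \code{t}, \code{df}, \code{p_value}, \code{mean_diff},
#'   \code{n_pairs}, \code{n_dropped}. When all differences are identical and
#'   nonzero the statistic is +/-Inf and p is reported as the limit 0; when
#'   all differences are zero, t = 0 and p = 1.
#' @examples
#' paired_t_test(c(1, 2, 3), c(0, 0, 0))
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  ok <- !is.na(x) & !is.na(y)
  dropped <- sum(!ok)
  if (dropped > 0) message(dropped, " incomplete pair(s) dropped")
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs")
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  list(t = t_stat, df = n - 1, p_value = p, mean_diff = m,
       n_pairs = n, n_dropped = dropped)
}

#' Bonferroni correction
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with \code{p_raw}, \code{p_adjusted} (= min(1, m p)) and
#'   logical \code{significant}.
#' @examples
#' bonferroni(c(0.01, 0.2), alpha = 0.05)
#' @export
bonferroni <- function(p, alpha = 0.05) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- pmin(1, length(p) * p)
  data.frame(p_raw = p, p_adjusted = adj, significant = adj <= alpha)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \eqn{BC(u, v) = \sum_k |u_k - v_k| / \sum_k (u_k + v_k)}: 0 for identical
#' vectors, 1 for disjoint supports.
#'
#' @param u,v non-negative abundance vectors of equal length.
#' @param binary reduce to presence/absence before computing (literature
#'   reports are often presence-only).
#' @return dissimilarity in [0, 1].
#' @examples
#' bray_curtis(c(1, 2, 3), c(3, 2, 1)) # 1/3
#' @export
bray_curtis <- function(u, v, binary = FALSE) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  if (any(u < 0) || any(v < 0)) stop("abundances must be non-negative")
  if (binary) {
    u <- as.numeric(u > 0)
    v <- as.numeric(v > 0)
  }
  denom <- sum(u + v)
  if (denom == 0) stop("both vectors are all-zero; dissimilarity undefined")
  sum(abs(u - v)) / denom
}

#' Bray-Curtis dissimilarity matrix for a community table
#'
#' @param x samples x taxa abundance matrix (rows are communities).
#' @param binary presence/absence mode.
#' @return square symmetric matrix of pairwise dissimilarities with zero
#'   diagonal, labelled by rownames of \code{x}.
#' @export
bray_curtis_matrix <- function(x, binary = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples")
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- bray_curtis(x[i, ], x[j, ], binary = binary)
    }
  }
  d
}

# sum over groups of within-group sum_{i<j} d^2_ij / n_g
ss_within_groups <- function(d2, groups) {
  s <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      s <- s + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
  }
  s
}

permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  g <- length(unique(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- ss_within_groups(d2, groups)
  ss_between <- ss_total - ss_within
  f <- (ss_between / (g - 1)) / (ss_within / (n - g))
  list(f = f, r2 = ss_between / ss_total,
       ss_total = ss_total, ss_within = ss_within, ss_between = ss_between)
}

#' One-way permutational multivariate analysis of variance (PerMANOVA)
#'
#' Partitions the sum of squared dissimilarities among and within groups
#' directly from the distance matrix (no coordinates needed):
#' \eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / n}, \eqn{SS_{within} = \sum_g
#' \sum_{i<j \in g} d_{ij}^2 / n_g}, pseudo-F =
#' \eqn{(SS_{between}/(g-1)) / (SS_{within}/(n-g))}. Significance comes from
#' random permutations of the group labels; the p-value uses the +1
#' correction \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})}. On Euclidean
#' distances of univariate data the pseudo-F equals the classical one-way
#' ANOVA F.
#'
#' @param dist square symmetric dissimilarity matrix with zero diagonal (e.g.
#'   from \code{\link{bray_curtis_matrix}}).
#' @param groups factor-like group labels, one per sample; at least two
#'   groups, and residual degrees of freedom \code{n - g} must be positive.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed; permutation results are reproducible given the
#'   same seed and no global RNG state is disturbed.
#' @return object of class \code{phrag_permanova}: list with \code{pseudo_F},
#'   \code{r_squared}, \code{p_value}, \code{n_permutations}, \code{seed},
#'   \code{ss} (total/between/within), \code{df}.
#' @examples
#' m <- rbind(a1 = c(5, 0), a2 = c(6, 1), b1 = c(0, 5), b2 = c(1, 6))
#' d <- bray_curtis_matrix(m)
#' permanova(d, c("a", "a", "b", "b"), n_permutations = 99, seed = 1)$r_squared
#' @export
permanova <- function(dist, groups, n_permutations = 999, seed = 1) {
  dist <- as.matrix(dist)
  check_distance_matrix(dist)
  n <- nrow(dist)
  groups <- as.character(groups)
  if (length(groups) != n) stop("one group label per sample required")
  g <- length(unique(groups))
  if (g < 2) stop("need at least two groups")
  if (n - g <= 0) stop("no residual degrees of freedom (n - g <= 0)")
  d2 <- dist^2
  obs <- permanova_f(d2, groups)
  perm_f <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      permanova_f(d2, sample(groups))$f
    }, numeric(1))
  })
  p <- (1 + sum(perm_f >= obs$f)) / (1 + n_permutations)
  structure(list(pseudo_F = obs$f, r_squared = obs$r2, p_value = p,
                 n_permutations = n_permutations, seed = seed,
                 ss = c(total = obs$ss_total, between = obs$ss_between,
                        within = obs$ss_within),
                 df = c(between = g - 1, within = n - g)),
            class = "phrag_permanova")
}

#' @export
print.phrag_permanova <- function(x, ...) {
  cat(sprintf("PerMANOVA: pseudo-F = %.4f, r^2 = %.3f, p = %.4g (%d permutations, seed %d)\n",
              x$pseudo_F, x$r_squared, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

check_distance_matrix <- function(d, tol = 1e-8) {
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(d < -tol)) stop("distance matrix must be non-negative")
  if (any(abs(diag(d)) > tol)) stop("distance matrix must have zero diagonal")
  if (any(abs(d - t(d)) > tol)) stop("distance matrix must be symmetric")
  invisible(TRUE)
}

# principal-coordinate embedding retaining real and "imaginary" axes
# (negative eigenvalues), following the standard correction where squared
# distances in the negative-eigenvalue space are subtracted.
pcoa_axes <- function(d, tol = 1e-8) {
  n <- nrow(d)
  a <- -0.5 * d^2
  centering <- diag(n) - matrix(1 / n, n, n)
  gmat <- centering %*% a %*% centering
  e <- eigen((gmat + t(gmat)) / 2, symmetric = TRUE)
  pos <- e$values > tol
  neg <- e$values < -tol
  list(
    pos = e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos)),
    neg = e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), sum(neg))
  )
}

# Weiszfeld iteration for the L1 spatial median of rows of x
spatial_median <- function(x, iter = 200, tol = 1e-10) {
  if (nrow(x) == 1) return(x[1, ])
  m <- colMeans(x)
  for (i in seq_len(iter)) {
    w <- sqrt(rowSums(sweep(x, 2, m)^2))
    if (any(w < tol)) return(m) # median coincides with a point
    w <- 1 / w
    m_new <- colSums(x * w) / sum(w)
    if (sum((m_new - m)^2) < tol^2) return(m_new)
    m <- m_new
  }
  m
}

#' Multivariate group-dispersion check
#'
#' Tests whether groups differ in spread rather than location (the standard
#' caveat for a significant PerMANOVA on unbalanced designs). Samples are
#' embedded by principal-coordinate analysis, each sample's distance to its
#' group's spatial median (or centroid) is computed with the usual correction
#' for negative eigenvalues, and the one-way ANOVA F on those distances is
#' compared against permutations of the distances across groups.
#'
#' @inheritParams permanova
#' @param type \code{"median"} (spatial median, robust default) or
#'   \code{"centroid"}.
#' @return list with \code{group_dispersion} (named mean distance-to-center
#'   per group), \code{distances} (per sample), \code{F}, \code{p_value},
#'   \code{n_permutations}, \code{seed}.
#' @export
dispersion_check <- function(dist, groups, n_permutations = 999, seed = 1,
                             type = c("median", "centroid")) {
  type <- match.arg(type)
  dist <- as.matrix(dist)
  check_distance_matrix(dist)
  n <- nrow(dist)
  groups <- as.character(groups)
  if (length(groups) != n) stop("one group label per sample required")
  if (length(unique(groups)) < 2) stop("need at least two groups")
  ax <- pcoa_axes(dist)
  z <- numeric(n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    center_fun <- if (type == "median") spatial_median else colMeans
    d2 <- 0
    if (ncol(ax$pos) > 0) {
      cpos <- center_fun(ax$pos[idx, , drop = FALSE])
      d2 <- d2 + rowSums(sweep(ax$pos[idx, , drop = FALSE], 2, cpos)^2)
    }
    if (ncol(ax$neg) > 0) {
      cneg <- center_fun(ax$neg[idx, , drop = FALSE])
      d2 <- d2 - rowSums(sweep(ax$neg[idx, , drop = FALSE], 2, cneg)^2)
    }
    z[idx] <- sqrt(pmax(d2, 0))
  }
  f_of <- function(zv) {
    grand <- mean(zv)
    ssb <- 0; ssw <- 0
    for (g in unique(groups)) {
      zi <- zv[groups == g]
      ssb <- ssb + length(zi) * (mean(zi) - grand)^2
      ssw <- ssw + sum((zi - mean(zi))^2)
    }
    gn <- length(unique(groups))
    if (ssw == 0) return(if (ssb == 0) 0 else Inf)
    (ssb / (gn - 1)) / (ssw / (n - gn))
  }
  f_obs <- f_of(z)
  perm_f <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) f_of(sample(z)), numeric(1))
  })
  p <- (1 + sum(perm_f >= f_obs)) / (1 + n_permutations)
  disp <- vapply(split(z, groups), mean, numeric(1))
  list(group_dispersion = disp, distances = z, F = f_obs, p_value = p,
       n_permutations = n_permutations, seed = seed)
}
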