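# Nonparametric statistical battery: exact/approximate Wilcoxon
# signed-rank, Friedman, Steel-Dwass all-pairs, paired t, Pearson
# correlation with linear regression. Conventions: mid-ranks on ties,
# zero differences dropped (Wilcoxon's original convention), exact
# enumeration up to 15 nonzero differences.

.stat_result <- function(method, statistic, p_value, exact, n) {
  structure(list(method = method, statistic = statistic,
                 p_value = min(max(p_value, 0), 1), exact = exact,
                 n_effective = n),
            class = "stat_result")
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on paired differences. Zero differences are dropped;
#' ties in |d| receive mid-ranks. With `mode = "auto"` the null
#' distribution is enumerated exactly over all `2^m` sign assignments for
#' m <= 15 nonzero differences, otherwise a normal approximation with tie
#' correction is used.
#'
#' @param x,y equal-length paired measurements.
#' @param mode "auto", "exact" or "normal_approx".
#' @return a `stat_result` with the W+ statistic.
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  stopifnot(length(x) == length(y), length(x) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0)
    return(.stat_result("wilcoxon_signed_rank", 0, 1, TRUE, 0L))
  rk <- rank(abs(d))
  w_plus <- sum(rk[d > 0])
  exact <- switch(mode, exact = TRUE, normal_approx = FALSE, auto = m <= 15)
  if (exact) {
    # enumerate W+ over all sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    w_all <- as.vector(signs %*% rk)
    p <- 2 * min(mean(w_all <= w_plus), mean(w_all >= w_plus))
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(rk)
    sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  .stat_result("wilcoxon_signed_rank", w_plus, p, exact, m)
}

#' Friedman rank test for randomized blocks
#'
#' Within-block mid-ranks; statistic
#' `chi2_F = 12/(n k (k+1)) * sum(R_j^2) - 3 n (k+1)` referred to the
#' chi-square distribution with k-1 degrees of freedom.
#'
#' @param mat numeric matrix, blocks in rows, treatments in columns.
#' @return a `stat_result`.
#' @export
friedman_rank_test <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2) stop("need at least 2 treatments")
  if (n < 2) stop("need at least 2 blocks")
  ranks <- t(apply(mat, 1, rank))
  Rj <- colSums(ranks)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  .stat_result("friedman", stat, p, FALSE, n)
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For each pair of groups, the two-sample rank sum on the joint mid-rank
#' ordering is studentized with the tie-corrected exact variance and
#' referred to the studentized-range distribution over k groups
#' (`ptukey(sqrt(2) |t|, k, Inf)`), giving family-wise adjusted p-values.
#'
#' With `mode = "permutation"` the family-wise p-values are instead
#' estimated by permuting group labels and referring each pair's |t| to
#' the permutation distribution of the maximum |t| over all pairs.
#'
#' @param groups list of >= 3 numeric vectors, each of length >= 2.
#' @param mode "asymptotic" (studentized range) or "permutation".
#' @param n_perm permutations for the permutation mode.
#' @param perm_seed RNG seed for the permutation mode.
#' @return data.frame with one row per pair: group indices, statistic t,
#'   adjusted p, unadjusted two-group normal-approximation p.
#' @export
steel_dwass <- function(groups, mode = c("asymptotic", "permutation"),
                        n_perm = 1e4, perm_seed = 1L) {
  mode <- match.arg(mode)
  k <- length(groups)
  if (k < 3)
    stop("Steel-Dwass needs >= 3 groups; use a two-sample rank test instead")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs >= 2 observations")
  pairs <- utils::combn(k, 2)
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    statistic = NA_real_, p_adjusted = NA_real_,
                    p_unadjusted = NA_real_)
  for (q in seq_len(ncol(pairs))) {
    gi <- groups[[pairs[1, q]]]; gj <- groups[[pairs[2, q]]]
    ni <- length(gi); nj <- length(gj); N <- ni + nj
    r <- rank(c(gi, gj))
    Ri <- sum(r[seq_len(ni)])
    E <- ni * (N + 1) / 2
    V <- ni * nj / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
    if (V <= 0) {
      tstat <- 0; padj <- 1; punadj <- 1
    } else {
      tstat <- (Ri - E) / sqrt(V)
      padj <- stats::ptukey(sqrt(2) * abs(tstat), nmeans = k, df = Inf,
                            lower.tail = FALSE)
      punadj <- 2 * stats::pnorm(-abs(tstat))
    }
    res$statistic[q] <- tstat
    res$p_adjusted[q] <- padj
    res$p_unadjusted[q] <- punadj
  }
  if (mode == "permutation") {
    sizes <- vapply(groups, length, integer(1))
    starts <- c(0L, cumsum(sizes))
    pooled <- unlist(groups)
    tstat_pairs <- function(vals) {
      vapply(seq_len(ncol(pairs)), function(q) {
        a <- pairs[1, q]; b <- pairs[2, q]
        gi <- vals[(starts[a] + 1):starts[a + 1]]
        gj <- vals[(starts[b] + 1):starts[b + 1]]
        ni <- sizes[a]; nj <- sizes[b]; N <- ni + nj
        r <- rank(c(gi, gj))
        V <- ni * nj / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
        if (V <= 0) 0 else
          abs((sum(r[seq_len(ni)]) - ni * (N + 1) / 2) / sqrt(V))
      }, numeric(1))
    }
    t_obs <- abs(res$statistic)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(perm_seed))
    exceed <- numeric(length(t_obs))
    for (b in seq_len(n_perm)) {
      tmax <- max(tstat_pairs(sample(pooled)))
      exceed <- exceed + (tmax >= t_obs - 1e-12)
    }
    res$p_adjusted <- exceed / n_perm
  }
  res
}

#' Paired t test
#'
#' @param x,y equal-length paired measurements; the differences must have
#'   nonzero variance.
#' @return a `stat_result` with the t statistic (df = n - 1).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0)
    stop("differences have zero variance; paired t undefined")
  ht <- stats::t.test(x, y, paired = TRUE)
  .stat_result("paired_t", unname(ht$statistic), ht$p.value, FALSE,
               length(x))
}

#' Pearson correlation with least-squares regression
#'
#' @param x,y numeric vectors, length >= 3; `x` must vary.
#' @return list with `r`, `slope`, `intercept`, `p_value` (t transform of
#'   r), `n`.
#' @export
pearson_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("x is constant; regression degenerate")
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), p_value = ct$p.value,
       n = length(x))
}
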