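#' Exact Mann-Whitney U test
#'
#' Computes the U statistic of the first sample and a two-sided p-value. When
#' both samples have at most \code{enumerate_max} observations, the exact
#' null distribution of U is built by full enumeration of all
#' choose(n1+n2, n1) assignments of the pooled ranks to the first sample
#' (ties handled by average ranks); the two-sided p-value is twice the
#' smaller tail probability, capped at 1. For larger samples the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @param enumerate_max Per-group size limit for exact enumeration.
#' @return A list (class \code{"te_test"}): statistic (U), p_value, method,
#'   exact flag, n per group.
#' @examples
#' mwu_test(1:4, 5:8)$p_value  # 2/70 = 0.0286 (complete separation, 4 vs 4)
#' @export
mwu_test <- function(x, y, enumerate_max = 10) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= enumerate_max && n2 <= enumerate_max) {
    idx <- utils::combn(n, n1)
    Us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Us <= U + eps), mean(Us >= U - eps)))
    method <- "exact Mann-Whitney U (full enumeration)"
    exact <- TRUE
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
    exact <- FALSE
  }
  structure(list(statistic = U, p_value = p, method = method, exact = exact,
                 n = c(n1 = n1, n2 = n2)), class = "te_test")
}

#' Exact binomial sign test
#'
#' Exact two-sided binomial test of k successes in n trials. At p0 = 0.5 the
#' two-sided p-value is obtained by tail doubling,
#' 2 * min(P(X <= k), P(X >= k)), capped at 1 (the distribution is
#' symmetric).
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @return A \code{"te_test"} list with statistic k.
#' @examples
#' sign_test_binom(18, 23)$p_value  # 0.0106
#' @export
sign_test_binom <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n, n >= 1, p0 > 0, p0 < 1)
  lower <- stats::pbinom(k, n, p0)
  upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  p <- min(1, 2 * min(lower, upper))
  structure(list(statistic = k, p_value = p,
                 method = "exact binomial sign test (tail doubling)",
                 exact = TRUE, n = n), class = "te_test")
}

#' Spearman rank correlation with exact permutation p-value
#'
#' rho is the Pearson correlation of average ranks (equivalently
#' 1 - 6S/(n(n^2-1)) when there are no ties, with S the sum of squared rank
#' differences). For untied data with n at most \code{exact_n_max}, the
#' two-sided p-value is computed exactly by full enumeration of all n!
#' permutations: P(|rho_perm| >= |rho|). Otherwise the t approximation
#' t = rho * sqrt((n-2)/(1-rho^2)) on n-2 df is used.
#'
#' @param x,y Numeric vectors of equal length (>= 3 pairs).
#' @param exact_n_max Largest n for exact enumeration.
#' @return A \code{"te_test"} list with statistic rho and element S.
#' @export
spearman_test <- function(x, y, exact_n_max = 9) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rho undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  S <- sum((rx - ry)^2)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (!ties && n <= exact_n_max) {
    P <- all_permutations(n)
    denom <- n * (n^2 - 1)
    rhos <- 1 - 6 * colSums((t(P) - ry[order(rx)])^2) / denom
    # permuting one ranking against the other spans the full null
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "Spearman rank correlation (exact permutation)"
    exact <- TRUE
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "Spearman rank correlation (t approximation)"
    exact <- FALSE
  }
  structure(list(statistic = rho, S = S, p_value = p, method = method,
                 exact = exact, n = n), class = "te_test")
}

# all permutations of 1..n as an n! x n integer matrix (insertion recursion)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    q <- p + (p >= i)
    cbind(rep(i, nrow(q)), q)
  }))
}

#' @export
print.te_test <- function(x, ...) {
  cat(sprintf("%s\nstatistic = %.6g, p = %.4g%s\n", x$method,
              x$statistic, x$p_value,
              if (isTRUE(x$exact)) " (exact)" else ""))
  invisible(x)
}
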