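test_that("exact Mann-Whitney enumeration matches independent oracles", {
  # complete separation, 4 vs 4: p = 2/70
  expect_equal(mwu_test(1:4, 5:8)$p_value, 2 / 70)
  # identical multisets -> p = 1
  expect_equal(mwu_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # U = 7 with 4 vs 4: p = 62/70
  t7 <- mwu_test(c(1, 4, 5, 7), c(2, 3, 6, 8))
  expect_equal(t7$statistic, 7)
  expect_equal(t7$p_value, 62 / 70)
  expect_true(t7$exact)
  expect_error(mwu_test(numeric(0), 1:3), "non-empty")

  # untied instances across all n1, n2 <= 6: agreement with wilcox.test exact
  set.seed(47)
  for (n1 in 2:6) for (n2 in 2:6) {
    x <- sample(seq(1, 1000), n1); y <- sample(seq(1001, 2000), n2)
    x <- x + runif(n1); y <- y + runif(n2)
    ours <- mwu_test(x, y)
    ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }

  # tied instance against a brute-force pair-counting enumeration oracle
  x <- c(1, 2, 2, 5); y <- c(2, 3, 4)
  ours <- mwu_test(x, y)
  pool <- c(x, y)
  idx <- utils::combn(7, 4)
  Uof <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  Us <- apply(idx, 2, function(i) Uof(pool[i], pool[-i]))
  U <- Uof(x, y)
  expect_equal(ours$statistic, U)
  expect_equal(ours$p_value,
               min(1, 2 * min(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9))))

  # large samples fall back to the tie-corrected normal approximation
  big <- mwu_test(rnorm(50), rnorm(50, 0.5))
  expect_false(big$exact)
  expect_true(big$p_value > 0 && big$p_value < 1)
})

test_that("the exact binomial sign test reproduces tail doubling", {
  # printed values are truncated to four decimals (0.010622, 0.034690)
  expect_equal(sign_test_binom(18, 23)$p_value, 0.0106, tolerance = 5e-3)
  expect_equal(sign_test_binom(17, 23)$p_value, 0.0346, tolerance = 5e-3)
  expect_equal(sign_test_binom(10, 20)$p_value, 1)
  # agreement with stats::binom.test at p0 = 0.5
  for (k in c(0, 3, 11, 18, 23))
    expect_equal(sign_test_binom(k, 23)$p_value,
                 binom.test(k, 23)$p.value, tolerance = 1e-12)
  # symmetry k <-> n-k
  for (k in 0:12)
    expect_equal(sign_test_binom(k, 23)$p_value,
                 sign_test_binom(23 - k, 23)$p_value)
})

test_that("Spearman rho and its exact permutation p-value are correct", {
  # frozen fixture with S = 134 at n = 8: rho = 1 - 804/504 = -0.5952
  y <- c(7, 8, 5, 4, 2, 3, 1, 6)
  s <- spearman_test(1:8, y)
  expect_equal(s$S, 134)
  expect_equal(s$statistic, 1 - 6 * 134 / (8 * 63), tolerance = 1e-12)
  expect_equal(round(s$statistic, 3), -0.595)

  perfect <- spearman_test(1:8, 2 * (1:8) + 3)
  expect_equal(perfect$statistic, 1)
  expect_equal(perfect$p_value, 2 / factorial(8))
  expect_equal(spearman_test(1:8, 8:1)$statistic, -1)

  expect_error(spearman_test(1:2, 2:3), "3 pairs")
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")

  # exact p agrees with cor.test's exact algorithm for n in 5..8
  set.seed(53)
  for (n in 5:8) for (rep in 1:3) {
    x <- sample(n); yy <- sample(n)
    if (sd(x) == 0 || sd(yy) == 0) next
    ours <- spearman_test(x, yy)
    ref <- suppressWarnings(cor.test(x, yy, method = "spearman",
                                     exact = TRUE))
    expect_true(ours$exact)
    expect_equal(ours$statistic, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }

  # ties fall back to the t approximation
  tied <- spearman_test(c(1, 1, 2, 3, 4, 5), c(2, 1, 4, 3, 6, 5))
  expect_false(tied$exact)
})

test_that("logistic fits recover simulated coefficients and flag separation", {
  set.seed(59)
  # null: no association; |z| < 2 for ~95% of seeds
  hits <- replicate(100, {
    n <- 300
    d <- data.frame(y = rbinom(n, 1, 0.5), len = rnorm(n), eff = rnorm(n))
    f <- logistic_fit(y ~ len + eff, d)
    all(abs(f$coefficients[-1, "z value"]) < 2)
  })
  expect_gte(mean(hits), 0.85)

  # recovery of beta_effect = -1 at n = 1000
  n <- 1000
  eff <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 - 1 * eff))
  f <- logistic_fit(y ~ eff, data.frame(y = y, eff = eff))
  expect_lt(abs(f$coefficients["eff", "Estimate"] + 1), 0.2)
  expect_true(f$converged)
  expect_false(f$separation)

  # complete separation raises the flag
  d <- data.frame(y = rep(c(0, 1), each = 10), x = c(1:10, 21:30))
  fs <- logistic_fit(y ~ x, d)
  expect_true(fs$separation)

  expect_error(logistic_fit(y ~ x, data.frame(y = rep(1, 20), x = rnorm(20))),
               "constant response")
  expect_error(logistic_fit(y ~ x, data.frame(y = c(0, 1), x = 1:2)),
               "fewer than")
})

test_that("sequential ANOVA equals the normal-equations oracle", {
  set.seed(61)
  n <- 40
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 1 + 2 * d$x1 - 3 * d$x2 + rnorm(n)
  fit <- lm_anova(y ~ x1 + x2, d)
  X <- cbind(1, d$x1, d$x2)
  beta <- solve(crossprod(X), crossprod(X, d$y))
  expect_equal(unname(fit$coefficients[, "Estimate"]), drop(beta),
               tolerance = 1e-10)

  # orthogonal balanced design: sequential F equals marginal t^2
  g <- rep(c(-1, 1), each = 20)
  h <- rep(c(-1, 1), times = 20)
  d2 <- data.frame(g = g, h = h, y = 1 + g - 2 * h + rnorm(40))
  fit2 <- lm_anova(y ~ g + h, d2)
  expect_equal(fit2$anova[["F value"]][1:2],
               unname(fit2$coefficients[2:3, "t value"]^2),
               tolerance = 1e-10)

  # noiseless limit recovers coefficients exactly
  d3 <- data.frame(x = 1:10, y = 3 + 0.5 * (1:10))
  fit3 <- suppressWarnings(lm_anova(y ~ x, d3))  # perfect-fit warning expected
  expect_equal(unname(fit3$coefficients[, "Estimate"]), c(3, 0.5),
               tolerance = 1e-10)

  expect_error(lm_anova(y ~ x + I(2 * x), data.frame(x = 1:10, y = rnorm(10))),
               "rank-deficient")
})

test_that("PGLS on a star tree reproduces OLS and validates labels", {
  star <- ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:1", 1:8), collapse = ","), ");"))
  set.seed(67)
  d <- data.frame(x = rnorm(8), row.names = star$tip.label)
  d$y <- 2 + 0.7 * d$x + rnorm(8, 0, 0.2)
  pg <- pgls_brownian(y ~ x, d, star)
  ols <- lm(y ~ x, d)
  expect_equal(unname(pg$coefficients[, "Value"]), unname(coef(ols)),
               tolerance = 1e-8)
  rownames(d)[1] <- "zz"
  expect_error(pgls_brownian(y ~ x, d, star, labels = rownames(d)), "labels")
})

test_that("the eight-genome tree parses with the expected tips", {
  tr <- subgroup_tree()
  expect_equal(length(tr$tip.label), 8)
  expect_setequal(tr$tip.label,
                  c("Dsim_strain1", "Dsim_strain2", "Dmau", "Dmel",
                    "Dyak_strain1", "Dyak_strain2", "Dsan", "Dtei"))
  expect_true(all(tr$edge.length > 0))
})

test_that("the gene-wise screen is calibrated under the null and detects shifts", {
  tree_tips <- 8
  effect <- stats::setNames(c(2.5, 2.8, 1.2, 1.0, 1.4, 2.2, 2.6, 1.1),
                            sprintf("g%d", 1:8))
  complexes <- rep(c("mel", "yak"), each = 4)

  # constant genes are excluded
  set.seed(71)
  er <- matrix(sample(100, 8 * 30, replace = TRUE), 30, 8,
               dimnames = list(sprintf("gene%02d", 1:30), names(effect)))
  er[1, ] <- 50  # constant across genomes
  scr <- suvar_screen(er, effect, sprintf("gene%02d", 2:6), complexes)
  expect_false("gene01" %in% scr$per_gene$gene_id)
  expect_error(suvar_screen(er[, 1:3], effect[1:3], "gene02", complexes[1:3]),
               "4 genomes")

  # null calibration: MWU p-values roughly uniform across seeds
  ps <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    m <- matrix(runif(8 * 200), 200, 8,
                dimnames = list(sprintf("n%03d", 1:200), names(effect)))
    m <- t(apply(m, 1, rank))
    colnames(m) <- names(effect)
    suvar_screen(m, effect, sprintf("n%03d", 1:20),
                 complexes)$tests$mwu_rho$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.05)

  # constructed negative-rho shift in the candidate set is detected
  set.seed(73)
  n_other <- 2000; n_cand <- 50
  base <- t(replicate(n_other, rank(runif(8))))
  cand <- t(replicate(n_cand, rank(-effect + rnorm(8, 0, 1))))
  m <- rbind(base, cand)
  rownames(m) <- c(sprintf("o%04d", seq_len(n_other)),
                   sprintf("sv%03d", seq_len(n_cand)))
  colnames(m) <- names(effect)
  scr2 <- suvar_screen(m, effect, sprintf("sv%03d", seq_len(n_cand)),
                       complexes)
  expect_lt(scr2$tests$mwu_rho$p_value, 0.01)
  expect_lt(scr2$tests$ks_rho$p.value, 0.01)
  expect_lt(mean(scr2$per_gene$rho[scr2$per_gene$candidate]),
            mean(scr2$per_gene$rho[!scr2$per_gene$candidate]))
})
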