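#' Logistic regression of TE population frequency class
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via \code{stats::glm}) of a binary response -- typically the
#' population frequency class, low = 0 / high = 1 -- on predictors such as
#' TE length and the magnitude or extent of the TE's epigenetic effect.
#' Complete separation and non-convergence are flagged rather than silently
#' reported.
#'
#' @param formula Model formula with a binary (0/1, logical or two-level
#'   factor) response.
#' @param data data.frame with the model variables.
#' @param min_n Minimum number of observations (the per-family screen uses
#'   10); fewer rows is an error.
#' @return A list: coefficients (matrix with estimate, se, z, p), converged,
#'   separation flag, n, and the underlying \code{glm} fit.
#' @export
logistic_fit <- function(formula, data, min_n = 10) {
  mf <- stats::model.frame(formula, data)
  if (nrow(mf) < min_n)
    stop("fewer than ", min_n, " observations")
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (length(unique(y[!is.na(y)])) < 2) stop("constant response")
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  eps <- 1e-8
  fv <- stats::fitted(fit)
  if (all(fv < eps | fv > 1 - eps)) separation <- TRUE
  list(coefficients = stats::coef(summary(fit)),
       converged = fit$converged, separation = separation,
       n = nrow(mf), fit = fit)
}

#' Ordinary least squares with sequential (type-I) ANOVA
#'
#' Fits the linear model and reports sequential F tests in the order the
#' predictors appear in the formula, e.g. TE abundance ~ species complex +
#' epigenetic effect tests the effect after accounting for the complex.
#'
#' @param formula Model formula.
#' @param data data.frame.
#' @return A list: coefficients (summary matrix), anova (sequential ANOVA
#'   table) and the \code{lm} fit.
#' @export
lm_anova <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  fit <- stats::lm(formula, data = data)
  p <- length(stats::coef(fit))
  if (nrow(mf) < p + 2) stop("need n >= p + 2 observations")
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design")
  list(coefficients = stats::coef(summary(fit)),
       anova = stats::anova(fit), fit = fit)
}

#' Phylogenetic generalized least squares under Brownian motion
#'
#' Generalized least squares with residual covariance proportional to shared
#' branch length between tips (Brownian motion on the supplied tree), with
#' sequential F tests as in \code{\link{lm_anova}} under the GLS transform.
#' Implemented with \code{nlme::gls} and \code{ape::corBrownian}.
#'
#' @param formula Model formula.
#' @param data data.frame; rows must correspond to tree tips.
#' @param tree An \code{ape::phylo} tree whose tip labels match
#'   \code{labels}.
#' @param labels Tip label of each data row (default: rownames of
#'   \code{data}).
#' @return A list: coefficients (tTable with estimate, se, t, p and 95% CI),
#'   anova (sequential F table), and the \code{gls} fit.
#' @export
pgls_brownian <- function(formula, data, tree, labels = rownames(data)) {
  if (!setequal(labels, tree$tip.label) ||
      length(labels) != length(tree$tip.label))
    stop("data labels do not match the tree tip labels")
  d <- data
  d$.tip <- labels
  fit <- nlme::gls(formula, data = d,
                   correlation = ape::corBrownian(1, phy = tree,
                                                  form = ~.tip))
  tt <- summary(fit)$tTable
  df_resid <- nrow(d) - nrow(tt)
  crit <- stats::qt(0.975, df_resid)
  ci <- cbind(lower = tt[, "Value"] - crit * tt[, "Std.Error"],
              upper = tt[, "Value"] + crit * tt[, "Std.Error"])
  list(coefficients = cbind(tt, ci), anova = stats::anova(fit), fit = fit)
}

#' Eight-genome phylogeny of the studied strains
#'
#' The working phylogeny for the eight genomes (two strains each of
#' D. simulans and D. yakuba plus D. mauritiana, D. melanogaster,
#' D. santomea and D. teissieri), with arbitrary branch lengths, used for
#' the Brownian-motion correlation structure in the between-species
#' regressions.
#'
#' @return An \code{ape::phylo} object with 8 tips.
#' @export
subgroup_tree <- function() {
  ape::read.tree(text = paste0(
    "((((Dsim_strain1:0.1,Dsim_strain2:0.1):0.15,Dmau:0.25):3,Dmel:3.25)",
    ":7.25,(((Dyak_strain1:0.1,Dyak_strain2:0.1):0.9,Dsan:1):1.75,",
    "Dtei:2.75):7.75);"))
}

#' Gene-wise screen for heterochromatin-modifier associations
#'
#' For every gene, associates its expression rank across genomes with the
#' genome-level mean magnitude of TE-mediated enrichment: (i) the Spearman
#' rank correlation rho and (ii) the expression coefficient from the
#' regression genome effect ~ expression rank + species complex. The
#' candidate gene set (e.g. Su(var) genes, whose products build or maintain
#' heterochromatin) is compared to all other genes by Mann-Whitney U and
#' two-sample Kolmogorov-Smirnov (asymptotic) tests, and genes in the most
#' negative 5% / 10% of either metric are flagged.
#'
#' @param expression_ranks Numeric matrix, genes x genomes, of expression
#'   ranks (rank 1 = highest expressed), with genome columns named.
#' @param genome_effect Named numeric vector: mean magnitude per genome.
#' @param candidate_ids Gene ids of the candidate (Su(var)) set.
#' @param complex_labels Factor/character of species-complex membership per
#'   genome, aligned with \code{genome_effect}.
#' @return A list: per_gene data.frame (gene_id, rho, coef, candidate,
#'   top5_rho, top10_rho, top5_coef, top10_coef), and tests (MWU and KS for
#'   both metrics).
#' @export
suvar_screen <- function(expression_ranks, genome_effect, candidate_ids,
                         complex_labels) {
  genomes <- names(genome_effect)
  if (length(genomes) < 4)
    stop("need at least 4 genomes for a rank correlation screen")
  stopifnot(all(genomes %in% colnames(expression_ranks)),
            length(complex_labels) == length(genome_effect))
  er <- expression_ranks[, genomes, drop = FALSE]
  cl <- factor(complex_labels)
  if (any(table(cl) < 2)) stop("need >= 2 genomes per species complex")
  keep <- apply(er, 1, function(v) !anyNA(v) && stats::sd(v) > 0)
  er <- er[keep, , drop = FALSE]
  rho <- apply(er, 1, function(v) stats::cor(v, genome_effect,
                                             method = "spearman"))
  coef_expr <- apply(er, 1, function(v) {
    stats::coef(stats::lm(genome_effect ~ v + cl))[["v"]]
  })
  per_gene <- data.frame(gene_id = rownames(er), rho = rho, coef = coef_expr,
                         candidate = rownames(er) %in% candidate_ids,
                         stringsAsFactors = FALSE)
  per_gene$top5_rho <- per_gene$rho <= stats::quantile(per_gene$rho, 0.05)
  per_gene$top10_rho <- per_gene$rho <= stats::quantile(per_gene$rho, 0.10)
  per_gene$top5_coef <- per_gene$coef <= stats::quantile(per_gene$coef, 0.05)
  per_gene$top10_coef <- per_gene$coef <= stats::quantile(per_gene$coef, 0.10)
  cand <- per_gene$candidate
  if (!any(cand) || all(cand))
    stop("candidate set must be a non-empty strict subset of the genes")
  tests <- list(
    mwu_rho = mwu_test(per_gene$rho[cand], per_gene$rho[!cand]),
    ks_rho = suppressWarnings(stats::ks.test(per_gene$rho[cand],
                                             per_gene$rho[!cand],
                                             exact = FALSE)),
    mwu_coef = mwu_test(per_gene$coef[cand], per_gene$coef[!cand]),
    ks_coef = suppressWarnings(stats::ks.test(per_gene$coef[cand],
                                              per_gene$coef[!cand],
                                              exact = FALSE)))
  list(per_gene = per_gene, tests = tests)
}
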