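#' Loiselle kinship matrix
#'
#' Multilocus kinship estimator of Loiselle and colleagues for a panel of
#' homozygous inbred lines: with `x_il` the indicator of the second allele in
#' line `i` at locus `l` and `p_l` its panel frequency among the `n_l`
#' informative lines,
#' \deqn{F_{ij} = \frac{\sum_l (x_{il}-p_l)(x_{jl}-p_l) + p_l(1-p_l)/(n_l-1)}
#'                     {\sum_l p_l(1-p_l)}}
#' with the sums running over the loci where both lines are informative
#' (pairwise-complete). Negative pair estimates are set to 0 (a negative
#' value only indicates a lower-than-random relationship); the diagonal is set
#' to 1 by convention, recorded in the `diagonal` attribute.
#'
#' @param panel a [genotype_panel].
#' @param het_as_missing treat heterozygous calls as missing (default).
#' @return symmetric lines x lines numeric matrix, attribute
#'   `diagonal = "fixed at 1"`.
#' @export
loiselle_kinship <- function(panel, het_as_missing = TRUE) {
  g <- hom_calls(panel, het_as_missing)
  obs <- !is.na(g)
  n_l <- colSums(obs)
  p <- colSums(g == 1L, na.rm = TRUE) / n_l
  poly <- !is.na(p) & p > 0 & p < 1 & n_l >= 2
  if (!any(poly)) stop("no polymorphic SNP available for kinship")
  g <- g[, poly, drop = FALSE]
  obs <- obs[, poly, drop = FALSE]
  p <- p[poly]
  n_l <- n_l[poly]
  xc <- sweep(g, 2, p)         # x - p, NA where missing
  xc[!obs] <- 0                # missing contributes nothing
  w <- p * (1 - p)             # per-locus denominator weight
  corr <- w / (n_l - 1)        # finite-sample correction per shared locus
  storage.mode(obs) <- "numeric"
  num <- tcrossprod(xc) + obs %*% (corr * t(obs))
  den <- obs %*% (w * t(obs))
  k <- num / den
  k[den == 0] <- NA_real_
  k[k < 0] <- 0                # negative estimates clipped to 0
  diag(k) <- 1
  dimnames(k) <- list(panel$line_ids, panel$line_ids)
  attr(k, "diagonal") <- "fixed at 1"
  k
}

#' PCA structure covariates
#'
#' Top principal-component scores of the centered allele-dosage matrix,
#' standing in for model-based ancestry coefficients as fixed structure
#' covariates in the mixed model. Missing dosages are imputed at the column
#' mean before centering (they then contribute nothing to the component).
#'
#' @param panel a [genotype_panel].
#' @param q number of axes (must satisfy `0 < q < min(lines, SNPs)`).
#' @return lines x q matrix of scores; column means are 0.
#' @export
pca_covariates <- function(panel, q = 2) {
  if (q <= 0) stop("`q` must be positive")
  if (q >= min(n_lines(panel), n_snps(panel)))
    stop("`q` must be smaller than both the line and SNP counts")
  g <- hom_calls(panel)
  mu <- colMeans(g, na.rm = TRUE)
  for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- mu[j]
  x <- scale(g, center = TRUE, scale = FALSE)
  pc <- stats::prcomp(x, center = FALSE, rank. = q)
  scores <- pc$x[, seq_len(q), drop = FALSE]
  rownames(scores) <- panel$line_ids
  scores
}

#' Multi-environment BLUP and heritability
#'
#' Fits `value = grand mean + environment (fixed) + line (random) + error`
#' by REML (via \pkg{lme4}) for one trait and returns the shrunken line
#' effects, the predicted genotypic values (intercept at the mean environment
#' plus line BLUP), and the variance components with heritability
#' `h2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)`.
#'
#' @param phenotypes a [phenotype_table].
#' @param trait trait code to fit.
#' @return list with `blup` (data.frame `line`, `trait`, `blup`, `ranef`)
#'   and `varcomp` (list `sigma_a2`, `sigma_e2`, `h2`). Lines observed in no
#'   environment are absent from `blup`.
#' @export
blup_across_envs <- function(phenotypes, trait) {
  d <- phenotypes[phenotypes$trait == trait & !is.na(phenotypes$value), ,
                  drop = FALSE]
  if (nrow(d) == 0) stop(sprintf("no records for trait '%s'", trait))
  if (length(unique(d$line)) < 2) stop("need at least 2 lines")
  d$line <- factor(d$line)
  d$env <- factor(d$env)
  fit <- if (nlevels(d$env) > 1) {
    lme4::lmer(value ~ env + (1 | line), data = d, REML = TRUE)
  } else {
    lme4::lmer(value ~ 1 + (1 | line), data = d, REML = TRUE)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_a2 <- vc$vcov[vc$grp == "line"]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  h2 <- sigma_a2 / (sigma_a2 + sigma_e2)
  re <- lme4::ranef(fit)$line
  fe <- lme4::fixef(fit)
  # genotypic value at the average environment effect
  env_mean <- if (nlevels(d$env) > 1) {
    mm <- colMeans(stats::model.matrix(~env, data = d)[, -1, drop = FALSE])
    fe[1] + sum(fe[-1] * mm)
  } else fe[1]
  blup <- data.frame(line = rownames(re), trait = trait,
                     blup = env_mean + re[[1]], ranef = re[[1]])
  rownames(blup) <- NULL
  list(blup = blup,
       varcomp = list(sigma_a2 = sigma_a2, sigma_e2 = sigma_e2, h2 = h2))
}
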