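test_that("Loiselle kinship: duplicates top their rows, negatives clipped,
           SNP order irrelevant", {
  sim <- small_sim(seed = 4)
  p <- sim$panel
  # append an exact duplicate of line 1
  calls <- rbind(p$calls, dup = p$calls[1, ])
  rownames(calls)[nrow(calls)] <- "dup_line"
  pd <- genotype_panel(calls, p$map, p$alleles)
  K <- loiselle_kinship(pd)
  expect_true(isSymmetric(unname(K)))
  expect_true(all(K >= 0))                       # clipping rule
  i <- which(rownames(K) == p$line_ids[1])
  j <- which(rownames(K) == "dup_line")
  off <- K[i, -i]
  expect_equal(unname(K[i, j]), max(off))        # self-similarity
  # kinship is invariant to SNP (column) order
  perm <- sample(ncol(p$calls))
  pp <- genotype_panel(p$calls[, perm], p$map[perm, ], p$alleles[perm, ])
  expect_equal(loiselle_kinship(pp), loiselle_kinship(p))
  expect_error(loiselle_kinship(panel_from_codes(matrix(0L, 4, 3))),
               "polymorphic")
})

test_that("within-population kinship exceeds between-population kinship", {
  sim <- simulate_panel(scenario_config(
    seed = 8, fst = 0.15, n_lines = c(landrace = 60, modern = 60),
    chromosomes = data.frame(name = "1A", length_cM = 100, n_snps = 120)))
  K <- loiselle_kinship(sim$panel)
  pop <- unname(sim$partition[rownames(K)])
  same <- outer(pop, pop, "==")
  diag(same) <- NA
  expect_gt(mean(K[same & !is.na(same)]), mean(K[!same & !is.na(same)]))
})

test_that("PCA covariates are centered and separate planted populations", {
  sim <- simulate_panel(scenario_config(
    seed = 12, fst = 0.25, n_lines = c(landrace = 50, modern = 50),
    chromosomes = data.frame(name = "1A", length_cM = 100, n_snps = 100)))
  Q <- pca_covariates(sim$panel, 2)
  expect_equal(unname(colMeans(Q)), c(0, 0), tolerance = 1e-10)
  pop <- unname(sim$partition[rownames(Q)])
  # axis-1 group means are well separated relative to within-group spread
  m <- tapply(Q[, 1], pop, mean)
  s <- tapply(Q[, 1], pop, sd)
  expect_gt(abs(diff(m)) / mean(s), 2)
  expect_error(pca_covariates(sim$panel, 0), "positive")
})

test_that("PCA on a single SNP is proportional to its dosage", {
  codes <- cbind(c(0L, 0L, 1L, 1L, 0L), c(0L, 1L, 0L, 1L, 0L))
  p <- panel_from_codes(codes)
  Q <- pca_covariates(p, 1)
  ctr <- codes[, 1] - mean(codes[, 1])
  # scores are collinear with the dominant centered dosage pattern
  expect_gt(abs(cor(Q[, 1], ctr + (codes[, 2] - mean(codes[, 2])))), 0.99)
})

test_that("BLUP recovers heritability across environments and shrinks", {
  sim <- simulate_panel(scenario_config(
    seed = 14, n_lines = c(landrace = 100, modern = 100),
    chromosomes = data.frame(name = "1A", length_cM = 80, n_snps = 60),
    h2 = 0.6))
  ph <- simulate_phenotypes(sim)
  fit <- blup_across_envs(ph$phenotypes, "TKW")
  expect_lt(abs(fit$varcomp$h2 - 0.6), 0.1)
  expect_gte(fit$varcomp$h2, 0)
  expect_lte(fit$varcomp$h2, 1)
  # random effects sum to ~0 and shrink toward zero in a balanced design
  expect_lt(abs(sum(fit$blup$ranef)), 1e-6 * sd(fit$blup$blup) *
              nrow(fit$blup))
  d <- ph$phenotypes
  raw <- tapply(d$value, d$line, mean) - mean(d$value)
  raw <- raw[fit$blup$line]
  expect_true(all(abs(fit$blup$ranef) <= abs(raw) + 1e-8))
})

test_that("permuting line labels drives the heritability estimate to zero", {
  sim <- simulate_panel(scenario_config(
    seed = 15, n_lines = c(landrace = 100, modern = 100),
    chromosomes = data.frame(name = "1A", length_cM = 80, n_snps = 60),
    h2 = 0.6))
  ph <- simulate_phenotypes(sim)
  d <- ph$phenotypes
  set.seed(1)
  # permute line labels independently within each environment: any line
  # effect is destroyed while environment effects are preserved
  for (e in unique(d$env))
    d$line[d$env == e] <- sample(d$line[d$env == e])
  fit <- blup_across_envs(phenotype_table(as.data.frame(d)), "TKW")
  expect_lt(fit$varcomp$h2, 0.1)
})

test_that("single-environment BLUPs approach centered observations as the
           residual variance vanishes", {
  set.seed(3)
  lines <- sprintf("L%03d", 1:80)
  g <- rnorm(80, sd = 3)
  d <- data.frame(line = rep(lines, 2), trait = "PH",
                  env = rep(c("E1", "E2"), each = 80),
                  value = 100 + rep(c(0, 1), each = 80) + rep(g, 2) +
                    rnorm(160, sd = 0.01))
  fit <- blup_across_envs(phenotype_table(d), "PH")
  expect_gt(fit$varcomp$h2, 0.99)
  expect_equal(unname(fit$blup$ranef), unname(g - mean(g)),
               tolerance = 0.02)
})
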