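test_that("significance rule reproduces the 1/n thresholds", {
  r <- significance_rule(4434)
  expect_equal(r$threshold, 2.3e-4)
  expect_equal(r$neglog10, 3.65)
  r <- significance_rule(847)
  expect_equal(r$threshold, 1.2e-3)
  expect_equal(r$neglog10, 2.93)
  expect_equal(significance_rule(100)$threshold, 1e-2)
})

# one shared scan fixture for the snp/block tests below
scan_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_panel(scenario_config(
        seed = 61, n_lines = c(landrace = 90, modern = 70),
        chromosomes = data.frame(name = "1A", length_cM = 100, n_snps = 80),
        missing_rate = 0.01))
      ph <- simulate_phenotypes(sim)
      fit <- blup_across_envs(ph$phenotypes, "TKW")
      cache <<- list(
        sim = sim,
        y = stats::setNames(fit$blup$blup, fit$blup$line),
        K = loiselle_kinship(sim$panel),
        Q = pca_covariates(sim$panel, 2))
    }
    cache
  }
})

test_that("snp_gwas excludes low-MAF markers and n reflects the exclusion", {
  fx <- scan_fixture()
  res <- snp_gwas(fx$sim$panel, fx$y, fx$Q, fx$K, maf = 0.05)
  maf <- minor_allele_frequency(fx$sim$panel)
  expect_equal(nrow(res), sum(maf >= 0.05, na.rm = TRUE))
  expect_equal(attr(res, "significance")$n_markers, nrow(res))
  expect_true(all(res$p_value > 0 & res$p_value <= 1, na.rm = TRUE))
  expect_true(all(res$r2_explained >= 0 & res$r2_explained <= 1))
  expect_true(all(res$maf >= 0.05))
})

test_that("favorable allele follows the trait orientation", {
  set.seed(67)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  y <- stats::setNames(10 + 2 * x + rnorm(n, sd = 0.5),
                       sprintf("L%02d", 1:n))
  codes <- cbind(as.integer(x), rbinom(n, 1, 0.5))
  p <- panel_from_codes(codes, line_ids = names(y))
  K <- diag(n); dimnames(K) <- list(names(y), names(y))
  up <- snp_gwas(p, y, K = K, maf = 0.05, larger_favorable = TRUE)
  dn <- snp_gwas(p, y, K = K, maf = 0.05, larger_favorable = FALSE)
  # allele coded 1 ("B") raises the trait
  expect_equal(up$favorable[up$marker == "S01"], "B")
  expect_equal(dn$favorable[dn$marker == "S01"], "A")
})

test_that("a two-haplotype block test matches the scan of its tag SNP when
           the tag indexes the haplotypes perfectly", {
  # a panel whose blocks all carry exactly two founder haplotypes, no
  # missing data: every polymorphic member SNP indexes the haplotypes
  sim <- simulate_panel(scenario_config(
    seed = 63, n_lines = c(landrace = 80, modern = 60),
    chromosomes = data.frame(name = "1A", length_cM = 80, n_snps = 50),
    n_haplotypes = 2, missing_rate = 0))
  ph <- simulate_phenotypes(sim)
  fit <- blup_across_envs(ph$phenotypes, "TKW")
  y <- stats::setNames(fit$blup$blup, fit$blup$line)
  K <- loiselle_kinship(sim$panel)
  null <- mlm_null(y, K = K)
  bl <- detect_blocks(sim$panel)
  hs <- enumerate_haplotypes(sim$panel, bl)
  blk <- haplotype_gwas(hs, y, K = K, null = null)
  b <- blk$marker[blk$n_classes == 2][1]
  members <- bl$snps[[match(b, bl$block_id)]]
  tag <- select_tag_snps(hs, b)
  expect_length(tag, 1)
  x <- stats::setNames(as.numeric(sim$panel$calls[, tag]),
                       sim$panel$line_ids)
  snp <- mlm_marker_test(null, x)
  expect_equal(blk$F[blk$marker == b], snp$F, tolerance = 1e-8)
  expect_equal(blk$p_value[blk$marker == b], snp$p_value, tolerance = 1e-8)
})

test_that("haplotype scan pools rare classes and applies the block MAF rule", {
  fx <- scan_fixture()
  bl <- detect_blocks(fx$sim$panel)
  hs <- enumerate_haplotypes(fx$sim$panel, bl)
  res <- haplotype_gwas(hs, fx$y, fx$Q, fx$K, maf = 0.05, pool_freq = 0.05)
  expect_true(all(res$maf >= 0.05))
  expect_true(all(res$n_classes >= 2))
  expect_true(all(res$p_value > 0 & res$p_value <= 1, na.rm = TRUE))
  # skipped + tested covers all blocks
  expect_equal(nrow(res) + length(attr(res, "skipped")), nrow(bl))
  expect_equal(attr(res, "significance")$n_markers, nrow(res))
})

test_that("a planted block QTL is detected and its effect recovered", {
  cfg <- scenario_config(
    seed = 71, n_lines = c(landrace = 150, modern = 150),
    chromosomes = data.frame(name = "1A", length_cM = 120, n_snps = 100),
    missing_rate = 0)
  sim <- simulate_panel(cfg)
  # plant +6 units on haplotype 2 of a block where that class is common
  # enough to estimate but not the baseline
  tb <- sim$truth$blocks
  f2 <- vapply(seq_len(nrow(tb)), function(b) {
    a <- sim$truth$assignments[, b]
    mean(a[!is.na(a)] == 2)
  }, numeric(1))
  fmax <- vapply(seq_len(nrow(tb)), function(b) {
    a <- sim$truth$assignments[, b]
    max(tabulate(a[!is.na(a)], 4)) / sum(!is.na(a))
  }, numeric(1))
  b <- which(f2 >= 0.15 & f2 <= 0.4 & f2 < fmax)[1]
  cfg$qtl <- data.frame(type = "block", chrom = "1A",
                        cM = (tb$start_cM[b] + tb$end_cM[b]) / 2,
                        haplotype = 2, effect = 6)
  ph <- simulate_phenotypes(sim, cfg)
  fit <- blup_across_envs(ph$phenotypes, "TKW")
  y <- stats::setNames(fit$blup$blup, fit$blup$line)
  K <- loiselle_kinship(sim$panel)
  Q <- pca_covariates(sim$panel, 2)
  res <- haplotype_gwas(enumerate_haplotypes(sim$panel,
                                             detect_blocks(sim$panel)),
                        y, Q, K)
  hit <- res[which.min(res$p_value), ]
  expect_lt(hit$p_value, attr(res, "significance")$threshold)
  # the detected block overlaps the planted one
  blocks <- detect_blocks(sim$panel)
  hb <- blocks[blocks$block_id == hit$marker, ]
  expect_true(hb$start_cM <= tb$end_cM[b] && hb$end_cM >= tb$start_cM[b])
  # the causal-class contrast recovers the planted effect within 1 unit
  effs <- as.numeric(sub(".*:", "", strsplit(hit$effects, ";")[[1]]))
  expect_lt(abs(max(effs) - 6), 1)
})

test_that("permuting the phenotype destroys planted associations", {
  fx <- scan_fixture()
  set.seed(73)
  miss <- 0
  for (rep in 1:5) {
    yp <- stats::setNames(sample(fx$y), names(fx$y))
    res <- snp_gwas(fx$sim$panel, yp, fx$Q, fx$K)
    thr <- attr(res, "significance")$threshold
    if (min(res$p_value, na.rm = TRUE) >= thr) miss <- miss + 1
  }
  expect_gte(miss, 4)
})
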