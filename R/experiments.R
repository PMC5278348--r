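#' One replicate of the block-versus-SNP detection experiment
#'
#' Demonstrates why haplotype-based association can detect loci that
#' single-SNP scans miss. A structured panel is generated with three-founder
#' haplotype pools per block; a block is selected whose pool contains an
#' "interior" haplotype — one that no single member SNP separates from both
#' other haplotypes (on a mutation chain `00 -> 01 -> 11` the middle
#' haplotype is interior) — and a QTL effect is planted on that haplotype.
#' Both scans are then run with the same Q + K mixed model and their
#' marker-count significance rules applied: the joint block test sees the
#' full haplotype partition while every member SNP only sees a diluted
#' two-group contrast.
#'
#' @param seed integer seed for this replicate.
#' @param n_lines named vector of lines per population.
#' @param n_snps SNPs on the single simulated chromosome.
#' @param effect planted QTL effect in trait units.
#' @param fst population differentiation of the panel.
#' @param h2 target heritability.
#' @param freq_range admissible pooled frequency range for the causal
#'   (interior) haplotype.
#' @param min_other_freq minimum pooled frequency of the two flanking
#'   haplotypes.
#' @param r2_max maximum admissible squared correlation between any member
#'   SNP dosage and the causal-haplotype indicator (computed from the pooled
#'   haplotype frequencies); low single-SNP taggability is the defining
#'   regime of the phenomenon.
#' @return list with `block_p` (p-value of the detected block covering the
#'   causal planted block), `block_threshold`, `snp_p` (p-values of the
#'   planted block's member SNPs in the genome-wide single-SNP scan),
#'   `snp_threshold`, `block_hit` (block significant), `snp_miss` (no member
#'   SNP significant), `success` (both), and the causal block bookkeeping.
#' @export
block_vs_snp_replicate <- function(seed,
                                   n_lines = c(landrace = 150, modern = 150),
                                   n_snps = 1600,
                                   effect = 1.7,
                                   fst = 0.06,
                                   h2 = 0.4,
                                   freq_range = c(0.05, 0.12),
                                   min_other_freq = 0.30,
                                   r2_max = 0.09) {
  cfg <- scenario_config(
    seed = seed, n_lines = n_lines,
    chromosomes = data.frame(name = "1A", length_cM = 180, n_snps = n_snps),
    n_haplotypes = 3L, fst = fst, h2 = h2, missing_rate = 0)
  sim <- simulate_panel(cfg)

  cand <- find_interior_haplotype(sim$truth, freq_range, min_other_freq,
                                  r2_max)
  if (is.null(cand))
    return(list(block_p = NA_real_, success = FALSE,
                reason = "no interior-haplotype block in admissible range"))

  cfg$qtl <- data.frame(type = "block", chrom = cand$chrom, cM = cand$cM,
                        haplotype = cand$haplotype, effect = effect)
  ph <- simulate_phenotypes(sim, cfg)
  fit <- blup_across_envs(ph$phenotypes, cfg$trait)
  y <- stats::setNames(fit$blup$blup, fit$blup$line)
  K <- loiselle_kinship(sim$panel)
  Q <- pca_covariates(sim$panel, 2)
  null <- mlm_null(y, Q, K)

  snp_res <- snp_gwas(sim$panel, y, Q, K, null = null)
  blocks <- detect_blocks(sim$panel)
  hapset <- enumerate_haplotypes(sim$panel, blocks)
  blk_res <- haplotype_gwas(hapset, y, Q, K, null = null)

  snp_thr <- attr(snp_res, "significance")$threshold
  blk_thr <- attr(blk_res, "significance")$threshold
  member_p <- snp_res$p_value[snp_res$marker %in% cand$snp_ids]
  # detected block(s) overlapping the causal planted interval
  hit_ids <- blocks$block_id[blocks$chrom == cand$chrom &
                               blocks$start_cM <= cand$end_cM &
                               blocks$end_cM >= cand$start_cM]
  block_p <- suppressWarnings(
    min(blk_res$p_value[blk_res$marker %in% hit_ids], na.rm = TRUE))
  if (!is.finite(block_p)) block_p <- NA_real_
  block_hit <- !is.na(block_p) && block_p < blk_thr
  snp_miss <- length(member_p) == 0 ||
    all(is.na(member_p) | member_p >= snp_thr)
  list(block_p = block_p, block_threshold = blk_thr,
       snp_p = member_p, snp_threshold = snp_thr,
       block_hit = block_hit, snp_miss = snp_miss,
       success = block_hit && snp_miss, causal = cand)
}

# Scan the truth record for a block whose pool holds an interior haplotype
# (separable from neither alternative by any single SNP, and in low r2 with
# every member SNP) at admissible pooled frequencies. Returns the candidate
# with the lowest worst-case single-SNP r2.
find_interior_haplotype <- function(truth, freq_range, min_other_freq,
                                    r2_max = 0.15) {
  best <- NULL
  best_score <- Inf
  for (b in seq_len(nrow(truth$blocks))) {
    pool <- truth$pools[[b]]
    a <- truth$assignments[, b]
    a <- a[!is.na(a)]
    if (length(a) == 0) next
    freqs <- tabulate(a, nbins = nrow(pool)) / length(a)
    for (h in seq_len(nrow(pool))) {
      sep <- vapply(seq_len(ncol(pool)), function(j)
        all(pool[-h, j] != pool[h, j]), logical(1))
      if (any(sep)) next                      # a single SNP isolates h
      if (freqs[h] < freq_range[1] || freqs[h] > freq_range[2]) next
      if (min(freqs[-h]) < min_other_freq) next
      # worst-case r2 between a member SNP dosage and the causal indicator
      fh <- freqs[h]
      r2_snp <- vapply(seq_len(ncol(pool)), function(j) {
        pz <- sum(freqs[pool[, j] == 1L])
        if (pz <= 0 || pz >= 1) return(0)
        (fh * (pool[h, j] - pz))^2 / (fh * (1 - fh) * pz * (1 - pz))
      }, numeric(1))
      if (max(r2_snp) > r2_max) next
      score <- max(r2_snp)
      if (score < best_score) {
        best_score <- score
        best <- list(block = b, haplotype = h,
                     chrom = truth$blocks$chrom[b],
                     cM = (truth$blocks$start_cM[b] +
                             truth$blocks$end_cM[b]) / 2,
                     start_cM = truth$blocks$start_cM[b],
                     end_cM = truth$blocks$end_cM[b],
                     snp_ids = truth$blocks$snp_ids[[b]],
                     freq = freqs[h])
      }
    }
  }
  best
}

#' Type-I error of the mixed-model scan on a null structured panel
#'
#' Generates a structured panel whose phenotype carries population structure
#' and a polygenic background but no QTL on the scanned chromosomes: the
#' background is confined to one half of the genome and the Q + K scan is
#' run on the other half, so every tested marker is truly null (markers on a
#' background-carrying chromosome tag their block-mates' effects and would
#' mildly inflate the rate — the usual leave-one-chromosome-out argument).
#' Reports the fraction of tested markers with `p < alpha`, which under a
#' correctly specified model sits inside the binomial sampling band around
#' `alpha`.
#'
#' @param seed integer seed.
#' @param n_markers SNPs tested (the same number again carries the
#'   polygenic background).
#' @param n_lines named vector of lines per population.
#' @param alpha nominal level (default 0.05).
#' @param fst,h2 panel differentiation and heritability.
#' @return list with `rate`, `n_markers`, `alpha`, `ci` (95% binomial
#'   interval around `alpha` for this marker count).
#' @export
mlm_type1_experiment <- function(seed, n_markers = 2000,
                                 n_lines = c(landrace = 100, modern = 100),
                                 alpha = 0.05, fst = 0.06, h2 = 0.5) {
  per <- ceiling(n_markers / 4)
  bg <- c("3A", "4A", "3B", "4B")      # background chromosomes (not tested)
  test_chr <- c("1A", "2A", "1B", "2B")
  cfg <- scenario_config(
    seed = seed, n_lines = n_lines,
    chromosomes = data.frame(name = c(test_chr, bg),
                             length_cM = 160, n_snps = per),
    fst = fst, h2 = h2, missing_rate = 0, polygenic_chroms = bg)
  sim <- simulate_panel(cfg)
  ph <- simulate_phenotypes(sim)
  y01 <- ph$phenotypes[ph$phenotypes$env == cfg$environments$env[1], ]
  y <- stats::setNames(y01$value, y01$line)
  K <- loiselle_kinship(sim$panel)
  Q <- pca_covariates(sim$panel, 2)
  scan_panel <- subset_panel(
    sim$panel, snps = sim$panel$map$snp_id[sim$panel$map$chrom %in% test_chr])
  res <- snp_gwas(scan_panel, y, Q, K, maf = 0.05)
  rate <- mean(res$p_value < alpha, na.rm = TRUE)
  m <- sum(!is.na(res$p_value))
  list(rate = rate, n_markers = m, alpha = alpha,
       ci = alpha + c(-1, 1) * 1.96 * sqrt(alpha * (1 - alpha) / m))
}
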