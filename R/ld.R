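#' Pairwise linkage disequilibrium between two SNPs
#'
#' On a panel of homozygous inbred lines two-locus haplotype frequencies are
#' counted directly from the lines (no EM phasing is needed): a line that is
#' homozygous at both SNPs carries one observable two-locus haplotype.
#' Heterozygous calls are treated as missing by the inbred convention;
#' missing data are handled by pairwise-complete deletion, and the number of
#' informative lines is recorded.
#'
#' With `A`/`a` the alleles at the first SNP and `B`/`b` at the second,
#' `D = p_AB - p_A p_B`; `D' = |D| / D_max` with
#' `D_max = min(p_A p_b, p_a p_B)` when `D > 0` and
#' `min(p_A p_B, p_a p_b)` when `D < 0`; `r^2 = D^2 / (p_A p_a p_B p_b)`.
#' The unsigned `|D'|` is reported (the solid-spine rule is sign-free).
#'
#' @param panel a [genotype_panel].
#' @param snp_i,snp_j SNP ids.
#' @return one-row data.frame with columns `snp_i`, `snp_j`, `distance_cM`,
#'   `dprime`, `r2`, `n_informative`. `dprime`/`r2` are `NA` when either SNP
#'   is monomorphic among the informative lines (the pair is then treated as
#'   uninformative by block detection).
#' @examples
#' p <- sim_panel_small()
#' pairwise_ld(p, p$snp_ids[1], p$snp_ids[2])
#' @export
pairwise_ld <- function(panel, snp_i, snp_j) {
  x <- hom_calls(panel)[, snp_i]
  y <- hom_calls(panel)[, snp_j]
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  st <- ld_from_haplotype_counts(sum(x[ok] == 1 & y[ok] == 1),
                                 sum(x[ok] == 1 & y[ok] == 0),
                                 sum(x[ok] == 0 & y[ok] == 1),
                                 sum(x[ok] == 0 & y[ok] == 0))
  pos <- panel$map$cM[match(c(snp_i, snp_j), panel$map$snp_id)]
  data.frame(snp_i = snp_i, snp_j = snp_j,
             distance_cM = abs(pos[1] - pos[2]),
             dprime = st$dprime, r2 = st$r2, n_informative = n)
}

# D', r2 from two-locus haplotype counts (AB, Ab, aB, ab).
ld_from_haplotype_counts <- function(n_ab11, n_ab10, n_ab01, n_ab00) {
  n <- n_ab11 + n_ab10 + n_ab01 + n_ab00
  if (n < 2) return(list(dprime = NA_real_, r2 = NA_real_))
  pA <- (n_ab11 + n_ab10) / n
  pB <- (n_ab11 + n_ab01) / n
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(list(dprime = NA_real_, r2 = NA_real_))
  d <- n_ab11 / n - pA * pB
  dmax <- if (d > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (d == 0) 0 else abs(d) / dmax
  r2 <- d^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(dprime = min(dprime, 1), r2 = min(r2, 1))
}

# Vectorised all-pairs LD on one chromosome. Returns square matrices.
# Pairs with fewer than `min_informative` lines, or monomorphic at either
# SNP among shared lines, get NA.
ld_matrices <- function(panel, chromosome, min_informative = 2) {
  ids <- panel$map$snp_id[panel$map$chrom == chromosome]
  if (length(ids) < 2)
    stop(sprintf("chromosome '%s' has fewer than 2 mapped SNPs", chromosome))
  g <- hom_calls(panel)[, ids, drop = FALSE]
  obs <- !is.na(g)
  x1 <- g == 1L & obs
  x0 <- g == 0L & obs
  storage.mode(x1) <- "numeric"
  storage.mode(x0) <- "numeric"
  n11 <- crossprod(x1)            # both allele1
  n10 <- crossprod(x1, x0)        # i allele1, j allele0
  n01 <- crossprod(x0, x1)
  n00 <- crossprod(x0)
  n <- n11 + n10 + n01 + n00
  pa <- (n11 + n10) / n           # allele1 freq at SNP i among shared lines
  pb <- (n11 + n01) / n           # allele1 freq at SNP j
  d <- n11 / n - pa * pb
  dmax_pos <- pmin(pa * (1 - pb), (1 - pa) * pb)
  dmax_neg <- pmin(pa * pb, (1 - pa) * (1 - pb))
  dmax <- ifelse(d > 0, dmax_pos, dmax_neg)
  dprime <- ifelse(d == 0, 0, abs(d) / dmax)
  r2 <- d^2 / (pa * (1 - pa) * pb * (1 - pb))
  bad <- n < pmax(min_informative, 2) | pa %in% c(0, 1) | pb %in% c(0, 1)
  dprime[bad] <- NA_real_
  r2[bad] <- NA_real_
  dprime <- pmin(dprime, 1)
  r2 <- pmin(r2, 1)
  dimnames(dprime) <- dimnames(r2) <- dimnames(n) <- list(ids, ids)
  pos <- panel$map$cM[match(ids, panel$map$snp_id)]
  list(snp_ids = ids, cM = pos, dprime = dprime, r2 = r2, n = n)
}

#' All-pairs LD on a chromosome
#'
#' Computes `|D'|`, `r^2` and informative-line counts for every SNP pair on a
#' chromosome (optionally capped at a maximum cM distance), pairwise-complete
#' on missing data.
#'
#' @param panel a [genotype_panel].
#' @param chromosome chromosome label.
#' @param max_distance_cM keep only pairs closer than this (default: all).
#' @return data.frame with one row per pair: `snp_i`, `snp_j`, `distance_cM`,
#'   `dprime`, `r2`, `n_informative`, ordered by map position.
#' @export
ld_matrix <- function(panel, chromosome, max_distance_cM = NULL) {
  lm <- ld_matrices(panel, chromosome)
  m <- length(lm$snp_ids)
  ut <- which(upper.tri(lm$dprime), arr.ind = TRUE)
  out <- data.frame(snp_i = lm$snp_ids[ut[, 1]], snp_j = lm$snp_ids[ut[, 2]],
                    distance_cM = abs(lm$cM[ut[, 2]] - lm$cM[ut[, 1]]),
                    dprime = lm$dprime[ut], r2 = lm$r2[ut],
                    n_informative = lm$n[ut])
  if (!is.null(max_distance_cM))
    out <- out[out$distance_cM <= max_distance_cM, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' LD decay profile
#'
#' Bins pairwise statistics by map distance into intervals
#' `[k*w, (k+1)*w)` and reports the mean `r^2` and pair count per bin. Bins
#' with no pairs are reported with `NA` mean (empty, not zero).
#'
#' @param ld data.frame from [ld_matrix()] (columns `distance_cM`, `r2`).
#' @param bin_width_cM positive bin width in cM.
#' @return data.frame with `bin_start_cM`, `bin_end_cM`, `mean_r2`, `n_pairs`.
#' @export
ld_decay_profile <- function(ld, bin_width_cM) {
  if (!is.numeric(bin_width_cM) || bin_width_cM <= 0)
    stop("`bin_width_cM` must be positive")
  ld <- ld[!is.na(ld$r2), , drop = FALSE]
  if (nrow(ld) == 0) stop("no informative LD statistics to bin")
  k <- floor(ld$distance_cM / bin_width_cM)
  kmax <- max(k)
  mean_r2 <- rep(NA_real_, kmax + 1)
  n_pairs <- integer(kmax + 1)
  agg_n <- table(factor(k, levels = 0:kmax))
  agg_s <- tapply(ld$r2, factor(k, levels = 0:kmax), sum)
  n_pairs <- as.integer(agg_n)
  mean_r2 <- ifelse(n_pairs > 0, as.numeric(agg_s) / n_pairs, NA_real_)
  data.frame(bin_start_cM = (0:kmax) * bin_width_cM,
             bin_end_cM = (1:(kmax + 1)) * bin_width_cM,
             mean_r2 = mean_r2, n_pairs = n_pairs)
}
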