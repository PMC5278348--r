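# Shared fixtures and independent oracles for the test suite.

# Build a genotype_panel straight from 0/1/2/NA codes on one chromosome.
panel_from_codes <- function(codes, cM = NULL, chrom = "1A",
                             line_ids = NULL, snp_ids = NULL) {
  codes <- as.matrix(codes)
  if (is.null(line_ids)) line_ids <- sprintf("L%02d", seq_len(nrow(codes)))
  if (is.null(snp_ids)) snp_ids <- sprintf("S%02d", seq_len(ncol(codes)))
  dimnames(codes) <- list(line_ids, snp_ids)
  if (is.null(cM)) cM <- seq_len(ncol(codes))
  genotype_panel(codes, data.frame(snp_id = snp_ids, chrom = chrom, cM = cM))
}

# Expand two-locus haplotype counts (AB, Ab, aB, ab) into call vectors.
codes_from_counts <- function(n11, n10, n01, n00) {
  x <- c(rep(1L, n11), rep(1L, n10), rep(0L, n01), rep(0L, n00))
  y <- c(rep(1L, n11), rep(0L, n10), rep(1L, n01), rep(0L, n00))
  cbind(x, y)
}

# Independent LD oracle: exhaustive contingency counting plus the textbook
# D / D' / r2 formulas, written without reference to the package internals.
oracle_ld <- function(x, y) {
  keep <- !is.na(x) & !is.na(y) & x != 2 & y != 2
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  tab <- matrix(0, 2, 2)
  for (i in seq_len(n)) tab[x[i] + 1, y[i] + 1] <- tab[x[i] + 1, y[i] + 1] + 1
  pA <- sum(tab[2, ]) / n
  pB <- sum(tab[, 2]) / n
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    return(list(dprime = NA_real_, r2 = NA_real_, n = n))
  D <- tab[2, 2] / n - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(dprime = if (D == 0) 0 else abs(D) / dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
       n = n)
}

# Independent spine-block oracle: simulate the greedy left-to-right scan but
# evaluate every candidate interval with a from-scratch validity check
# (double loop over interior markers), independent of the incremental scan.
oracle_spine_blocks <- function(d, thr) {
  m <- nrow(d)
  valid <- function(i, j) {
    ok <- function(v) !is.na(v) && v > thr
    if (!ok(d[i, j])) return(FALSE)
    if (j - i >= 2)
      for (k in (i + 1):(j - 1))
        if (!ok(d[i, k]) || !ok(d[k, j])) return(FALSE)
    TRUE
  }
  first <- integer(); last <- integer()
  i <- 1L
  while (i < m) {
    j <- i
    while (j < m && valid(i, j + 1L)) j <- j + 1L
    if (j > i) {
      first <- c(first, i); last <- c(last, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(first = first, last = last)
}

# Brute-force minimal tag set: smallest subset of SNP columns whose joint
# pattern distinguishes all pairs of haplotype strings.
oracle_min_tag_size <- function(strings) {
  hmat <- do.call(rbind, strsplit(strings, ""))
  m <- ncol(hmat)
  for (size in 1:m) {
    for (subset in utils::combn(m, size, simplify = FALSE)) {
      keys <- apply(hmat[, subset, drop = FALSE], 1, paste, collapse = "")
      if (!anyDuplicated(keys)) return(size)
    }
  }
  m
}

# Random symmetric D' matrix mixing high/low LD and occasional NAs.
random_dprime_matrix <- function(m) {
  d <- matrix(stats::runif(m * m), m, m)
  hi <- matrix(stats::runif(m * m) < 0.4, m, m)
  d[hi] <- stats::runif(sum(hi), 0.8, 1)
  if (stats::runif(1) < 0.3) d[sample.int(m * m, max(1, m %/% 2))] <- NA
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  diag(d) <- 1
  d
}

small_sim <- function(seed = 7, ...) {
  simulate_panel(scenario_config(
    seed = seed,
    n_lines = c(landrace = 60, modern = 40),
    chromosomes = data.frame(name = "1A", length_cM = 80, n_snps = 60),
    ...))
}
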