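#' Single-SNP mixed-model association scan
#'
#' Runs the Q + K mixed linear model with P3D (variance components estimated
#' once on the null model, then reused per marker) over every SNP passing the
#' MAF filter. Inbred lines are coded as 0/1 allele dosage; heterozygous and
#' missing calls are omitted per marker. The marker-count significance rule
#' `P < 1/n` is attached, with `n` the number of markers actually tested.
#'
#' @param panel a [genotype_panel].
#' @param y named numeric phenotype vector (single environment values or
#'   BLUPs), names = line ids.
#' @param Q optional structure covariates (lines x q, rownamed).
#' @param K kinship matrix.
#' @param maf minor-allele-frequency cutoff (default 0.05).
#' @param larger_favorable is a larger trait value favorable? Determines the
#'   favorable-allele call from the allele group means (default `TRUE`).
#' @param null optional prefitted [mlm_null()] object to reuse.
#' @return data.frame of class `association_result` with one row per tested
#'   SNP: `marker`, `maf`, `n_used`, `F`, `p_value`, `neglog10p`,
#'   `r2_explained` (one-way ANOVA `SSA/SST`), `effect` (allele-1 effect
#'   from the GLS fit), `favorable` (allele symbol). Attributes:
#'   `significance` (the [significance_rule()]) and `null` (the fitted null).
#' @export
snp_gwas <- function(panel, y, Q = NULL, K, maf = 0.05,
                     larger_favorable = TRUE, null = NULL) {
  y <- y[!is.na(y)]
  lines <- intersect(names(y), panel$line_ids)
  if (length(lines) < 10) stop("need at least 10 phenotyped panel lines")
  y <- y[lines]
  sub <- subset_panel(panel, lines = lines)
  m <- minor_allele_frequency(sub)
  keep <- !is.na(m) & m >= maf
  snps <- sub$snp_ids[keep]
  if (length(snps) == 0) stop("no SNP passes the MAF filter")
  if (is.null(null)) null <- mlm_null(y, Q, K)
  g <- hom_calls(sub)
  rows <- lapply(snps, function(s) {
    x <- g[, s]
    names(x) <- sub$line_ids
    tst <- mlm_marker_test(null, x)
    r2 <- marker_r2(y[null$lines], x[null$lines])
    eff <- if (is.null(tst$effects)) NA_real_ else unname(tst$effects[1])
    fav <- favorable_allele(y[null$lines], x[null$lines],
                            sub$alleles[s, ], larger_favorable)
    data.frame(marker = s, maf = m[s], n_used = tst$n_used, F = tst$F,
               p_value = tst$p_value,
               neglog10p = -log10(tst$p_value),
               r2_explained = r2, effect = eff, favorable = fav)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "significance") <- significance_rule(nrow(out))
  attr(out, "null") <- null
  class(out) <- c("association_result", "data.frame")
  out
}

favorable_allele <- function(y, x, alleles, larger_favorable) {
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) return(NA_character_)
  mu <- tapply(y[ok], factor(x[ok], levels = 0:1), mean)
  if (anyNA(mu)) return(alleles[which(!is.na(mu))])
  best <- if (larger_favorable) which.max(mu) else which.min(mu)
  unname(alleles[best])
}

#' Haplotype-block mixed-model association scan
#'
#' Treats each block as one multi-allelic marker: the block MAF is the
#' frequency of the second-most-common haplotype; haplotypes rarer than
#' `pool_freq` among the phenotyped lines are pooled into an `other` class;
#' the block enters the model as indicator columns for every class except the
#' most common (the baseline), tested jointly by an F-test with P3D variance
#' components. Per-haplotype effects are contrasts against the baseline; the
#' favorable haplotype is the class with the largest trait-increasing (or
#' -decreasing, per `larger_favorable`) effect, the baseline counting as
#' effect 0. Lines unassigned at a block are omitted for that block.
#'
#' @param hapset a `haplotype_set` from [enumerate_haplotypes()].
#' @inheritParams snp_gwas
#' @param pool_freq rare-haplotype pooling threshold (default 0.05).
#' @return data.frame of class `association_result` with one row per tested
#'   block: `marker`, `maf`, `n_classes`, `n_used`, `F`, `p_value`,
#'   `neglog10p`, `r2_explained`, `effects` (semicolon list of
#'   `class:effect`), `favorable` (haplotype label; indices match the
#'   haplotype table, `other` is the pooled class). Attributes as in
#'   [snp_gwas()]; blocks skipped (fewer than 2 classes after pooling) are
#'   listed in attribute `skipped`.
#' @export
haplotype_gwas <- function(hapset, y, Q = NULL, K, maf = 0.05,
                           pool_freq = 0.05, larger_favorable = TRUE,
                           null = NULL) {
  y <- y[!is.na(y)]
  lines <- intersect(names(y), hapset$panel_lines)
  if (length(lines) < 10) stop("need at least 10 phenotyped lines")
  y <- y[lines]
  if (is.null(null)) null <- mlm_null(y, Q, K)
  rows <- list()
  skipped <- character()
  for (b in hapset$blocks$block_id) {
    a <- hapset$assignments[lines, b]
    tab <- sort(table(a), decreasing = TRUE)
    if (length(tab) < 2) { skipped <- c(skipped, b); next }
    freqs <- as.numeric(tab) / sum(tab)
    block_maf <- freqs[2]
    if (block_maf < maf) { skipped <- c(skipped, b); next }
    cls <- names(tab)
    rare <- cls[freqs < pool_freq]
    lab <- as.character(a)
    lab[lab %in% rare] <- "other"
    tab2 <- sort(table(lab), decreasing = TRUE)
    if (length(tab2) < 2) { skipped <- c(skipped, b); next }
    baseline <- names(tab2)[1]
    others <- names(tab2)[-1]
    design <- vapply(others, function(cl) as.numeric(lab == cl),
                     numeric(length(lab)))
    design[is.na(a), ] <- NA_real_
    rownames(design) <- lines
    colnames(design) <- others
    tst <- mlm_marker_test(null, design)
    r2 <- marker_r2(y[null$lines], lab[match(null$lines, lines)])
    eff <- tst$effects
    eff_str <- if (is.null(eff)) NA_character_ else
      paste(sprintf("%s:%+.4g", names(eff), eff), collapse = ";")
    fav <- if (is.null(eff) || anyNA(eff)) NA_character_ else {
      all_eff <- c(stats::setNames(0, baseline), eff)
      names(all_eff)[if (larger_favorable) which.max(all_eff)
                     else which.min(all_eff)]
    }
    rows[[b]] <- data.frame(marker = b, maf = block_maf,
                            n_classes = length(tab2), n_used = tst$n_used,
                            F = tst$F, p_value = tst$p_value,
                            neglog10p = -log10(tst$p_value),
                            r2_explained = r2, effects = eff_str,
                            favorable = fav)
  }
  if (length(rows) == 0) stop("no block passes the MAF filter")
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "significance") <- significance_rule(nrow(out))
  attr(out, "null") <- null
  attr(out, "skipped") <- skipped
  class(out) <- c("association_result", "data.frame")
  out
}

#' @export
print.association_result <- function(x, ...) {
  sig <- attr(x, "significance")
  cat(sprintf(
    "association_result: %d markers tested; P < 1/n = %g (-log10 = %.2f)\n",
    sig$n_markers, sig$threshold, sig$neglog10))
  n_sig <- sum(x$p_value < sig$threshold, na.rm = TRUE)
  cat(sprintf("  significant at P < 1/n: %d\n", n_sig))
  print.data.frame(utils::head(as.data.frame(x)[
    order(x$p_value), , drop = FALSE], 5))
  invisible(x)
}

#' Markers passing the 1/n significance rule
#'
#' @param result an `association_result`.
#' @return the significant rows, ordered by p-value.
#' @export
significant_markers <- function(result) {
  sig <- attr(result, "significance")
  out <- result[!is.na(result$p_value) & result$p_value < sig$threshold, ,
                drop = FALSE]
  out[order(out$p_value), , drop = FALSE]
}
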