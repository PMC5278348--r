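#' Genotype panel of homozygous inbred lines
#'
#' Container for a lines x SNPs matrix of biallelic calls together with a
#' genetic map (chromosome, position in centimorgan). Calls are stored as
#' integer codes: `0` = first allele, `1` = second allele, `2` = heterozygous,
#' `NA` = missing. The per-SNP allele symbols behind codes 0/1 are kept in an
#' `alleles` matrix so files round-trip exactly.
#'
#' SNPs are sorted by (chromosome, cM, snp_id); ties in cM are allowed
#' (co-located markers occur on dense genetic maps) and are broken by SNP id
#' for determinism.
#'
#' @param calls integer matrix, lines in rows and SNPs in columns, with
#'   dimnames giving line ids and SNP ids; values in `{0, 1, 2, NA}`.
#' @param map data.frame with columns `snp_id`, `chrom`, `cM`, one row per SNP.
#' @param alleles character matrix with one row per SNP (rownames = SNP ids)
#'   and two columns giving the symbols coded 0 and 1; the second symbol may
#'   be `NA` for a SNP where only one allele was observed.
#' @return An object of class `genotype_panel` with elements `line_ids`,
#'   `snp_ids`, `calls`, `alleles`, `map`.
#' @examples
#' calls <- rbind(L1 = c(0L, 0L), L2 = c(1L, NA))
#' colnames(calls) <- c("S1", "S2")
#' map <- data.frame(snp_id = c("S1", "S2"), chrom = "1A", cM = c(0, 2.5))
#' p <- genotype_panel(calls, map)
#' n_snps(p)
#' @export
genotype_panel <- function(calls, map, alleles = NULL) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("`calls` must carry line ids (rownames) and SNP ids (colnames)")
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  if (any(bad)) {
    idx <- which(bad)[1]
    stop(sprintf("invalid call code %s at line '%s', SNP '%s'",
                 calls[idx],
                 rownames(calls)[(idx - 1) %% nrow(calls) + 1],
                 colnames(calls)[(idx - 1) %/% nrow(calls) + 1]))
  }
  if (!all(c("snp_id", "chrom", "cM") %in% names(map)))
    stop("`map` must have columns snp_id, chrom, cM")
  map <- map[, c("snp_id", "chrom", "cM")]
  map$snp_id <- as.character(map$snp_id)
  map$chrom <- as.character(map$chrom)
  map$cM <- as.numeric(map$cM)

  dup <- duplicated(colnames(calls))
  if (any(dup))
    stop(sprintf("duplicate SNP id '%s'", colnames(calls)[which(dup)[1]]))
  multi <- unique(map$snp_id[duplicated(map$snp_id)])
  if (length(multi) > 0) {
    chr <- unique(map$chrom[map$snp_id == multi[1]])
    if (length(chr) > 1)
      stop(sprintf("SNP '%s' is mapped to more than one chromosome (%s)",
                   multi[1], paste(chr, collapse = ", ")))
    stop(sprintf("duplicate SNP id '%s' in map", multi[1]))
  }
  unmapped <- setdiff(colnames(calls), map$snp_id)
  if (length(unmapped) > 0)
    stop(sprintf("SNP '%s' has no map position", unmapped[1]))
  map <- map[match(colnames(calls), map$snp_id), ]
  if (anyNA(map$cM)) stop("non-numeric cM position in map")

  ord <- order(map$chrom, map$cM, map$snp_id)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  calls <- calls[, map$snp_id, drop = FALSE]

  if (is.null(alleles)) {
    alleles <- matrix(NA_character_, ncol(calls), 2,
                      dimnames = list(colnames(calls), c("allele0", "allele1")))
    alleles[, 1] <- "A"
    alleles[, 2] <- "B"
  } else {
    alleles <- as.matrix(alleles)
    colnames(alleles) <- c("allele0", "allele1")
    alleles <- alleles[map$snp_id, , drop = FALSE]
  }

  structure(list(line_ids = rownames(calls), snp_ids = colnames(calls),
                 calls = calls, alleles = alleles, map = map),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d lines x %d SNPs on %d chromosome(s)\n",
              length(x$line_ids), length(x$snp_ids),
              length(unique(x$map$chrom))))
  miss <- mean(is.na(x$calls))
  het <- mean(x$calls == 2L, na.rm = TRUE)
  cat(sprintf("  missing: %.1f%%  heterozygous: %.1f%%\n",
              100 * miss, 100 * het))
  invisible(x)
}

#' Panel dimensions
#' @param panel a [genotype_panel].
#' @return integer count.
#' @export
n_lines <- function(panel) length(panel$line_ids)

#' @rdname n_lines
#' @export
n_snps <- function(panel) length(panel$snp_ids)

#' Chromosomes present in a panel
#' @param panel a [genotype_panel].
#' @return character vector in map order.
#' @export
chromosomes <- function(panel) unique(panel$map$chrom)

#' Subset a panel by SNPs or lines
#'
#' Order of retained SNPs follows the panel map order, so subsetting never
#' reorders markers.
#'
#' @param panel a [genotype_panel].
#' @param snps,lines character vectors of ids to keep (`NULL` keeps all).
#' @return a [genotype_panel].
#' @export
subset_panel <- function(panel, snps = NULL, lines = NULL) {
  keep_s <- if (is.null(snps)) panel$snp_ids else
    panel$snp_ids[panel$snp_ids %in% snps]
  keep_l <- if (is.null(lines)) panel$line_ids else
    panel$line_ids[panel$line_ids %in% lines]
  if (length(keep_s) == 0) stop("no SNPs left after subsetting")
  if (length(keep_l) == 0) stop("no lines left after subsetting")
  genotype_panel(panel$calls[keep_l, keep_s, drop = FALSE],
                 panel$map[panel$map$snp_id %in% keep_s, ],
                 panel$alleles[keep_s, , drop = FALSE])
}

# Homozygous call codes: heterozygotes handled per the inbred convention
# (treated as missing by default since phase-free haplotypes require
# homozygous calls).
hom_calls <- function(panel, het_as_missing = TRUE) {
  m <- panel$calls
  if (het_as_missing) m[m == 2L] <- NA_integer_
  m
}

#' Minor allele frequency
#'
#' Computed over non-missing, non-heterozygous calls with each inbred line
#' counted once (haploid-equivalent counting). A SNP with no informative call
#' gets `NA` and is excluded by downstream filters.
#'
#' @param panel a [genotype_panel].
#' @param snps SNP ids (default: all SNPs).
#' @param het_as_missing treat heterozygous calls as missing (default `TRUE`);
#'   when `FALSE` a heterozygote contributes half a count to each allele.
#' @return named numeric vector of frequencies in `[0, 0.5]`.
#' @examples
#' p <- sim_panel_small()
#' head(minor_allele_frequency(p))
#' @export
minor_allele_frequency <- function(panel, snps = NULL, het_as_missing = TRUE) {
  m <- panel$calls
  if (!is.null(snps)) m <- m[, snps, drop = FALSE]
  if (het_as_missing) {
    mm <- m
    mm[mm == 2L] <- NA_integer_
    n1 <- colSums(mm == 1L, na.rm = TRUE)
    n <- colSums(!is.na(mm))
  } else {
    n1 <- colSums(m == 1L, na.rm = TRUE) + 0.5 * colSums(m == 2L, na.rm = TRUE)
    n <- colSums(!is.na(m))
  }
  p <- ifelse(n > 0, n1 / n, NA_real_)
  out <- pmin(p, 1 - p)
  names(out) <- colnames(m)
  out
}

#' Filter a panel on minor allele frequency
#'
#' Retains SNPs with MAF >= `threshold`; SNPs with undefined MAF (no
#' informative calls) are dropped. Map order is preserved and the number of
#' removed SNPs is reported as a message.
#'
#' @param panel a [genotype_panel].
#' @param threshold MAF cutoff in `[0, 0.5]`.
#' @inheritParams minor_allele_frequency
#' @return filtered [genotype_panel].
#' @export
filter_maf <- function(panel, threshold = 0.05, het_as_missing = TRUE) {
  if (threshold < 0 || threshold > 0.5)
    stop("`threshold` must be in [0, 0.5]")
  maf <- minor_allele_frequency(panel, het_as_missing = het_as_missing)
  keep <- !is.na(maf) & maf >= threshold
  if (!any(keep))
    stop(sprintf(
      "no SNP passes MAF >= %g; lower the threshold or check the panel",
      threshold))
  n_removed <- sum(!keep)
  if (n_removed > 0)
    message(sprintf("filter_maf: removed %d of %d SNPs (MAF < %g)",
                    n_removed, length(maf), threshold))
  subset_panel(panel, snps = panel$snp_ids[keep])
}

#' Population partition of panel lines
#'
#' @param labels named character vector: names are line ids, values are
#'   population labels.
#' @param panel optional [genotype_panel]; when given, every labeled line must
#'   exist in the panel.
#' @return named character vector of class `population_partition`.
#' @export
population_partition <- function(labels, panel = NULL) {
  if (is.null(names(labels)) || any(names(labels) == ""))
    stop("`labels` must be named by line id")
  labels <- vapply(labels, as.character, character(1))
  if (!is.null(panel)) {
    missing_lines <- setdiff(names(labels), panel$line_ids)
    if (length(missing_lines) > 0)
      stop(sprintf("labeled line '%s' is not in the panel", missing_lines[1]))
  }
  if (any(table(labels) < 1)) stop("each population needs at least one line")
  structure(labels, class = "population_partition")
}

#' Phenotype table in long format
#'
#' One record per (line, trait, environment); duplicates are an error. Values
#' must be finite or `NA` (missing).
#'
#' @param df data.frame with columns `line`, `trait`, `env`, `value`.
#' @return validated data.frame of class `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  need <- c("line", "trait", "env", "value")
  if (!all(need %in% names(df)))
    stop("phenotypes need columns line, trait, env, value")
  df <- df[, need]
  df$line <- as.character(df$line)
  df$trait <- as.character(df$trait)
  df$env <- as.character(df$env)
  df$value <- as.numeric(df$value)
  key <- paste(df$line, df$trait, df$env, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[which(duplicated(key))[1], ]
    stop(sprintf("duplicate record for line '%s', trait '%s', env '%s'",
                 d$line, d$trait, d$env))
  }
  if (any(is.infinite(df$value)))
    stop("phenotype values must be finite or NA")
  class(df) <- c("phenotype_table", "data.frame")
  df
}
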