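#' Gene diversity (expected heterozygosity)
#'
#' `1 - sum(p_i^2)` for allele (or haplotype) frequencies `p`.
#'
#' @param p numeric vector of frequencies summing to 1 (tolerance 1e-9).
#' @return value in `[0, 1)`.
#' @examples
#' gene_diversity(c(0.5, 0.5))
#' @export
gene_diversity <- function(p) {
  check_simplex(p)
  1 - sum(p^2)
}

#' Polymorphism information content
#'
#' Botstein's PIC: `1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`. Always at most
#' the gene diversity of the same frequencies.
#'
#' @inheritParams gene_diversity
#' @return PIC value.
#' @examples
#' pic(c(0.5, 0.5))  # 0.375
#' @export
pic <- function(p) {
  check_simplex(p)
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p_i^2)^2 - sum p_i^4, since cross terms
  # appear twice in the square
  1 - s2 - (s2^2 - s4)
}

check_simplex <- function(p) {
  if (any(p < 0)) stop("frequencies must be non-negative")
  if (abs(sum(p) - 1) > 1e-9)
    stop(sprintf("frequencies must sum to 1 (got %.12f)", sum(p)))
  invisible(p)
}

# Nei's Gst from per-population frequency vectors over a shared allele
# universe. Hs is weighted by informative line counts (POPGENE convention).
gst_from_freqs <- function(freq_list, n_list) {
  w <- unlist(n_list)
  keep <- w > 0
  freq_list <- freq_list[keep]
  w <- w[keep]
  if (length(w) < 2) return(list(Hs = NA_real_, Ht = NA_real_,
                                 gst = NA_real_))
  w <- w / sum(w)
  hs <- sum(w * vapply(freq_list, function(p) 1 - sum(p^2), numeric(1)))
  pbar <- Reduce(`+`, Map(`*`, freq_list, w))
  ht <- 1 - sum(pbar^2)
  gst <- if (ht > 0) (ht - hs) / ht else NA_real_
  list(Hs = hs, Ht = ht, gst = gst)
}

snp_freq_in_lines <- function(panel, snp, lines, het_as_missing = TRUE) {
  x <- hom_calls(panel, het_as_missing)[lines, snp]
  x <- x[!is.na(x)]
  n <- length(x)
  p1 <- if (n > 0) mean(x == 1L) else NA_real_
  list(p = c(1 - p1, p1), n = n)
}

#' Population differentiation (Nei's Gst) at SNP loci
#'
#' `Hs` is the within-population gene diversity averaged over populations
#' weighted by informative line counts; `Ht` the gene diversity of the pooled
#' (weighted) frequencies; `Gst = (Ht - Hs) / Ht`. Loci where `Ht = 0`
#' (monomorphic overall) get `NA`.
#'
#' @param panel a [genotype_panel].
#' @param partition a [population_partition].
#' @param snps SNP ids (default: all).
#' @return data.frame with `locus`, `Hs`, `Ht`, `gst`.
#' @export
fst_snps <- function(panel, partition, snps = NULL) {
  if (is.null(snps)) snps <- panel$snp_ids
  pops <- split(names(partition), unname(partition))
  if (length(pops) < 2) stop("need at least 2 populations")
  g <- hom_calls(panel)
  rows <- lapply(snps, function(s) {
    fr <- lapply(pops, function(ln) {
      x <- g[ln, s]
      x <- x[!is.na(x)]
      list(p = if (length(x)) c(mean(x == 0L), mean(x == 1L)) else c(NA, NA),
           n = length(x))
    })
    st <- gst_from_freqs(lapply(fr, `[[`, "p"), lapply(fr, `[[`, "n"))
    data.frame(locus = s, Hs = st$Hs, Ht = st$Ht, gst = st$gst)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# Haplotype frequencies of one block within a set of lines, over the block's
# global haplotype universe (indices of the haplotype_set table).
block_freq_in_lines <- function(hapset, block_id, lines) {
  a <- hapset$assignments[lines, block_id]
  a <- a[!is.na(a)]
  k <- nrow(hapset$haplotypes[[block_id]])
  p <- tabulate(a, nbins = max(k, 1))
  n <- length(a)
  list(p = if (n > 0) p / n else rep(NA_real_, max(k, 1)), n = n)
}

#' Population differentiation at haplotype blocks
#'
#' Treats each block haplotype as one allele of a multi-allelic marker and
#' applies the same Gst machinery as [fst_snps()]. Within-population
#' haplotype frequencies are recomputed from that population's assigned
#' lines only.
#'
#' @param hapset a `haplotype_set` from [enumerate_haplotypes()].
#' @param partition a [population_partition].
#' @param block_ids blocks to test (default: all).
#' @return data.frame with `locus`, `Hs`, `Ht`, `gst`.
#' @export
fst_blocks <- function(hapset, partition, block_ids = NULL) {
  if (is.null(block_ids)) block_ids <- hapset$blocks$block_id
  pops <- split(names(partition), unname(partition))
  if (length(pops) < 2) stop("need at least 2 populations")
  rows <- lapply(block_ids, function(b) {
    fr <- lapply(pops, function(ln) block_freq_in_lines(hapset, b, ln))
    st <- gst_from_freqs(lapply(fr, `[[`, "p"), lapply(fr, `[[`, "n"))
    data.frame(locus = b, Hs = st$Hs, Ht = st$Ht, gst = st$gst)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Per-block haplotype diversity within one population
#'
#' Gene diversity of a block's haplotype frequencies recomputed from the
#' named population's assigned lines.
#'
#' @inheritParams fst_blocks
#' @param population population label to profile.
#' @return named numeric vector by block id (`NA` where no line of the
#'   population is assigned).
#' @export
block_diversity <- function(hapset, partition, population) {
  lines <- names(partition)[unname(partition) == population]
  if (length(lines) == 0)
    stop(sprintf("no line labeled '%s'", population))
  vapply(hapset$blocks$block_id, function(b) {
    fr <- block_freq_in_lines(hapset, b, lines)
    if (fr$n == 0) NA_real_ else 1 - sum(fr$p^2)
  }, numeric(1))
}

#' Three-block sliding-window diversity profile
#'
#' Windows of three consecutive blocks are shifted along each chromosome one
#' block at a time (short arm to long arm, i.e. map order). The window index
#' is the arithmetic mean of the three blocks' haplotype gene diversities
#' within the named population (`mode = "mean"`), or the gene diversity of
#' the pooled haplotype classes of the three blocks (`mode = "pooled"`).
#' The window midpoint is the mean of the three block midpoints.
#'
#' @inheritParams block_diversity
#' @param chromosome chromosome label(s); default all.
#' @param mode `"mean"` (default) or `"pooled"`.
#' @return data.frame with `chrom`, `window`, `mid_cM`, `diversity`; zero
#'   rows (with a message) for chromosomes carrying fewer than 3 blocks.
#' @export
sliding_window_profile <- function(hapset, partition, population,
                                   chromosome = NULL,
                                   mode = c("mean", "pooled")) {
  mode <- match.arg(mode)
  blocks <- hapset$blocks
  chroms <- if (is.null(chromosome)) unique(blocks$chrom) else chromosome
  div <- block_diversity(hapset, partition, population)
  lines <- names(partition)[unname(partition) == population]
  out <- list()
  for (chr in chroms) {
    bl <- blocks[blocks$chrom == chr, , drop = FALSE]
    nb <- nrow(bl)
    if (nb < 3) {
      message(sprintf(
        "sliding_window_profile: chromosome '%s' has %d block(s); need 3",
        chr, nb))
      next
    }
    mid <- (bl$start_cM + bl$end_cM) / 2
    n_win <- nb - 2
    d <- numeric(n_win)
    for (wi in seq_len(n_win)) {
      idx <- wi:(wi + 2)
      if (mode == "mean") {
        d[wi] <- mean(div[bl$block_id[idx]], na.rm = TRUE)
      } else {
        # joint three-block haplotype per line (complete assignments only)
        a <- hapset$assignments[lines, bl$block_id[idx], drop = FALSE]
        complete <- rowSums(is.na(a)) == 0
        d[wi] <- if (!any(complete)) NA_real_ else {
          joint <- apply(a[complete, , drop = FALSE], 1, paste,
                         collapse = ":")
          p <- as.numeric(table(joint))
          p <- p / sum(p)
          1 - sum(p^2)
        }
      }
    }
    out[[chr]] <- data.frame(chrom = chr, window = seq_len(n_win),
                             mid_cM = vapply(seq_len(n_win), function(wi)
                               mean(mid[wi:(wi + 2)]), numeric(1)),
                             diversity = d)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), window = integer(),
                      mid_cM = numeric(), diversity = numeric()))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Per-SNP diversity statistics
#'
#' Gene diversity and PIC from the allele frequencies at each SNP (lines
#' counted once, heterozygotes/missing excluded).
#'
#' @param panel a [genotype_panel].
#' @param snps SNP ids (default: all).
#' @param lines line ids (default: all).
#' @return data.frame with `locus`, `n`, `gene_diversity`, `pic`.
#' @export
snp_diversity <- function(panel, snps = NULL, lines = NULL) {
  if (is.null(snps)) snps <- panel$snp_ids
  if (is.null(lines)) lines <- panel$line_ids
  g <- hom_calls(panel)[lines, snps, drop = FALSE]
  rows <- lapply(seq_along(snps), function(j) {
    x <- g[, j]
    x <- x[!is.na(x)]
    if (length(x) == 0)
      return(data.frame(locus = snps[j], n = 0L,
                        gene_diversity = NA_real_, pic = NA_real_))
    p <- c(mean(x == 0L), mean(x == 1L))
    p <- p[p > 0]
    data.frame(locus = snps[j], n = length(x),
               gene_diversity = gene_diversity(p), pic = pic(p))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
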