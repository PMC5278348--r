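#' Solid-spine haplotype block detection
#'
#' Implements the solid-spine-of-LD rule on a genetic map: an interval of
#' consecutive mapped SNPs `[i..j]` is a valid block when the first and the
#' last marker are in strong LD (`|D'|` strictly above the threshold) with
#' every intermediate marker and with each other — the intermediate markers
#' need not be in LD with one another. Blocks are found by a deterministic
#' greedy left-to-right scan: starting at the leftmost unblocked SNP the
#' right edge is extended one SNP at a time while the interval stays valid;
#' an interval of at least two SNPs is emitted and the scan continues after
#' it. Pairs with undefined LD (monomorphic, or fewer informative lines than
#' `min_informative`) count as failing the threshold.
#'
#' @param panel a [genotype_panel].
#' @param chromosome chromosome label(s); default all chromosomes.
#' @param dprime_threshold spine threshold on `|D'|`, strict inequality
#'   (default 0.8).
#' @param min_informative pairs observed in fewer lines are treated as
#'   uninformative (default 5; `|D'|` is unstable at tiny counts).
#' @return a `block_set`: data.frame with one row per block and columns
#'   `block_id` (`HapB-<chrom>-<index>`, index 1-based along the chromosome),
#'   `chrom`, `first`, `last` (SNP indices within the chromosome),
#'   `start_cM`, `end_cM`, `span_cM`, `n_snps`, and a list-column `snps` of
#'   member SNP ids in map order.
#' @examples
#' p <- sim_panel_small()
#' detect_blocks(p)
#' @export
detect_blocks <- function(panel, chromosome = NULL, dprime_threshold = 0.8,
                          min_informative = 5) {
  chroms <- if (is.null(chromosome)) chromosomes(panel) else chromosome
  missing_chr <- setdiff(chroms, chromosomes(panel))
  if (length(missing_chr) > 0)
    stop(sprintf("chromosome '%s' not present in panel", missing_chr[1]))
  out <- list()
  for (chr in chroms) {
    ids <- panel$map$snp_id[panel$map$chrom == chr]
    if (length(ids) < 2) next
    lm <- ld_matrices(panel, chr, min_informative = min_informative)
    iv <- spine_scan(lm$dprime, dprime_threshold)
    if (nrow(iv) == 0) next
    out[[chr]] <- data.frame(
      block_id = sprintf("HapB-%s-%d", chr, seq_len(nrow(iv))),
      chrom = chr, first = iv$first, last = iv$last,
      start_cM = lm$cM[iv$first], end_cM = lm$cM[iv$last],
      span_cM = lm$cM[iv$last] - lm$cM[iv$first],
      n_snps = iv$last - iv$first + 1L,
      snps = I(lapply(seq_len(nrow(iv)),
                      function(b) ids[iv$first[b]:iv$last[b]])))
  }
  res <- if (length(out) == 0) {
    data.frame(block_id = character(), chrom = character(),
               first = integer(), last = integer(), start_cM = numeric(),
               end_cM = numeric(), span_cM = numeric(), n_snps = integer(),
               snps = I(list()))
  } else do.call(rbind, c(out, make.row.names = FALSE))
  class(res) <- c("block_set", "data.frame")
  res
}

#' Spine scan on a precomputed `|D'|` matrix
#'
#' The scan underlying [detect_blocks()], exposed for matrix input: useful
#' for testing the spine semantics directly or for external LD sources.
#' `NA` entries fail the threshold.
#'
#' @param dprime_matrix square symmetric matrix of `|D'|` values for
#'   consecutive mapped SNPs.
#' @param dprime_threshold strict threshold (default 0.8).
#' @return data.frame with columns `first`, `last` (1-based SNP indices).
#' @export
detect_blocks_dprime <- function(dprime_matrix, dprime_threshold = 0.8) {
  spine_scan(dprime_matrix, dprime_threshold)
}

# Greedy left-to-right maximal extension under the spine validity rule.
spine_scan <- function(d, thr) {
  m <- nrow(d)
  pass <- function(v) !is.na(v) & v > thr
  first <- integer()
  last <- integer()
  i <- 1L
  while (i < m) {
    j <- i
    while (j < m) {
      # extend [i..j] to [i..j+1]: endpoints pair plus every interior marker
      # against the new right edge (interiors against i already hold)
      k <- j + 1L
      inner <- if (j > i) (i + 1L):j else integer()
      ok <- pass(d[i, k]) && all(pass(d[inner, k]))
      if (!ok) break
      j <- k
    }
    if (j > i) {
      first <- c(first, i)
      last <- c(last, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(first = first, last = last)
}

# Full validity predicate for an interval [i..j]; used by tests and by the
# post-hoc re-check in enumerate_haplotypes.
spine_valid_interval <- function(d, i, j, thr) {
  pass <- function(v) !is.na(v) & v > thr
  if (!pass(d[i, j])) return(FALSE)
  if (j - i >= 2) {
    inner <- (i + 1L):(j - 1L)
    if (!all(pass(d[i, inner])) || !all(pass(d[inner, j]))) return(FALSE)
  }
  # stepwise prefix chain, as built by the greedy scan
  if (j - i >= 2) {
    for (jj in (i + 1L):j) {
      if (!pass(d[i, jj])) return(FALSE)
      if (jj - i >= 2 && !all(pass(d[(i + 1L):(jj - 1L), jj]))) return(FALSE)
    }
  }
  TRUE
}

#' Enumerate block haplotypes and assign lines
#'
#' For each block, the distinct complete haplotype strings over the member
#' SNPs are counted among informative lines (lines homozygous and non-missing
#' at every member SNP). Haplotypes are numbered 1, 2, ... by descending
#' frequency, ties broken lexicographically by the haplotype string. A line
#' with any missing member call is unassigned — it never creates a haplotype.
#'
#' @param panel a [genotype_panel].
#' @param blocks a `block_set` from [detect_blocks()] on the same panel.
#' @return a `haplotype_set`: list with
#'   \describe{
#'     \item{`blocks`}{the input block table,}
#'     \item{`haplotypes`}{named list (by `block_id`) of data.frames with
#'       `haplotype` (index), `string` (member allele codes), `count`,
#'       `freq` (over assigned lines),}
#'     \item{`assignments`}{lines x blocks integer matrix of haplotype
#'       indices (`NA` = unassigned),}
#'     \item{`panel_lines`}{line ids.}
#'   }
#' @export
enumerate_haplotypes <- function(panel, blocks) {
  g <- hom_calls(panel)
  assign <- matrix(NA_integer_, n_lines(panel), nrow(blocks),
                   dimnames = list(panel$line_ids, blocks$block_id))
  haps <- vector("list", nrow(blocks))
  names(haps) <- blocks$block_id
  for (b in seq_len(nrow(blocks))) {
    gb <- g[, blocks$snps[[b]], drop = FALSE]
    complete <- rowSums(is.na(gb)) == 0
    strings <- rep(NA_character_, nrow(gb))
    strings[complete] <- apply(gb[complete, , drop = FALSE], 1, paste,
                               collapse = "")
    if (!any(complete)) {
      haps[[b]] <- data.frame(haplotype = integer(), string = character(),
                              count = integer(), freq = numeric())
      next
    }
    tab <- table(strings[complete])
    ord <- order(-as.integer(tab), names(tab))
    tab <- tab[ord]
    haps[[b]] <- data.frame(haplotype = seq_along(tab),
                            string = names(tab),
                            count = as.integer(tab),
                            freq = as.integer(tab) / sum(tab))
    assign[, b] <- match(strings, names(tab))
  }
  structure(list(blocks = blocks, haplotypes = haps, assignments = assign,
                 panel_lines = panel$line_ids),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d blocks, %d lines\n",
              nrow(x$blocks), length(x$panel_lines)))
  nh <- vapply(x$haplotypes, nrow, integer(1))
  if (length(nh) > 0)
    cat(sprintf("  haplotypes per block: mean %.2f, range %d-%d\n",
                mean(nh), min(nh), max(nh)))
  invisible(x)
}

#' Greedy tag-SNP selection for one block
#'
#' Selects a small set of member SNPs whose joint genotype distinguishes
#' every pair of common haplotypes (frequency >= `common_freq`). At each step
#' the SNP resolving the most still-confounded haplotype pairs is added; ties
#' go to the leftmost SNP on the map.
#'
#' @param hapset a `haplotype_set` from [enumerate_haplotypes()].
#' @param block_id block to tag.
#' @param common_freq haplotypes below this frequency are ignored
#'   (default 0.05).
#' @return character vector of tag SNP ids (subset of the block members).
#' @export
select_tag_snps <- function(hapset, block_id, common_freq = 0.05) {
  b <- match(block_id, hapset$blocks$block_id)
  if (is.na(b)) stop(sprintf("unknown block '%s'", block_id))
  hp <- hapset$haplotypes[[b]]
  members <- hapset$blocks$snps[[b]]
  hp <- hp[hp$freq >= common_freq, , drop = FALSE]
  if (nrow(hp) <= 1) return(members[1])
  hmat <- do.call(rbind, strsplit(hp$string, ""))
  pairs <- utils::combn(nrow(hp), 2)
  unresolved <- rep(TRUE, ncol(pairs))
  chosen <- integer()
  while (any(unresolved)) {
    gain <- vapply(seq_along(members), function(s) {
      if (s %in% chosen) return(-1L)
      sum(unresolved & hmat[pairs[1, ], s] != hmat[pairs[2, ], s])
    }, integer(1))
    best <- which.max(gain)  # ties -> leftmost (which.max takes the first)
    if (gain[best] <= 0) break  # no SNP separates the remaining pairs
    chosen <- c(chosen, best)
    unresolved <- unresolved & hmat[pairs[1, ], best] == hmat[pairs[2, ], best]
  }
  members[sort(chosen)]
}

#' Tag all blocks
#'
#' @inheritParams select_tag_snps
#' @return named list (by block id) of tag SNP id vectors.
#' @export
select_all_tags <- function(hapset, common_freq = 0.05) {
  stats::setNames(lapply(hapset$blocks$block_id, select_tag_snps,
                         hapset = hapset, common_freq = common_freq),
                  hapset$blocks$block_id)
}

#' Per-chromosome block summary and genome aggregates
#'
#' Builds the standard per-chromosome table (total SNPs, SNPs in blocks and
#' their percentage, range of block sizes, tag SNPs and percentage, block
#' count, mean and range of block span in cM, haplotype totals and means) and
#' genome-level aggregates via [aggregate_block_summary()].
#'
#' @param blocks a `block_set`.
#' @param hapset matching `haplotype_set`.
#' @param panel the [genotype_panel] the blocks were detected on.
#' @param tags optional precomputed tag list from [select_all_tags()].
#' @return list with `per_chrom` (data.frame, one row per chromosome) and
#'   `aggregates` (see [aggregate_block_summary()]).
#' @export
summarize_blocks <- function(blocks, hapset, panel, tags = NULL) {
  if (is.null(tags)) tags <- select_all_tags(hapset)
  chroms <- chromosomes(panel)
  rows <- lapply(chroms, function(chr) {
    bl <- blocks[blocks$chrom == chr, , drop = FALSE]
    total_snps <- sum(panel$map$chrom == chr)
    if (nrow(bl) == 0)
      return(data.frame(chrom = chr, total_snps = total_snps,
                        snps_in_blocks = 0L, pct_in_blocks = 0,
                        snps_per_block_min = NA_integer_,
                        snps_per_block_max = NA_integer_,
                        tag_snps = 0L, pct_tag = 0, n_blocks = 0L,
                        mean_span_cM = NA_real_, span_min_cM = NA_real_,
                        span_max_cM = NA_real_, total_haps = 0L,
                        mean_haps = NA_real_, haps_min = NA_integer_,
                        haps_max = NA_integer_))
    nh <- vapply(hapset$haplotypes[bl$block_id], nrow, integer(1))
    ntag <- sum(lengths(tags[bl$block_id]))
    data.frame(chrom = chr, total_snps = total_snps,
               snps_in_blocks = sum(bl$n_snps),
               pct_in_blocks = 100 * sum(bl$n_snps) / total_snps,
               snps_per_block_min = min(bl$n_snps),
               snps_per_block_max = max(bl$n_snps),
               tag_snps = ntag, pct_tag = 100 * ntag / total_snps,
               n_blocks = nrow(bl), mean_span_cM = mean(bl$span_cM),
               span_min_cM = min(bl$span_cM), span_max_cM = max(bl$span_cM),
               total_haps = sum(nh), mean_haps = mean(nh),
               haps_min = if (length(nh)) min(nh) else NA_integer_,
               haps_max = if (length(nh)) max(nh) else NA_integer_)
  })
  per_chrom <- do.call(rbind, c(rows, make.row.names = FALSE))
  list(per_chrom = per_chrom,
       aggregates = aggregate_block_summary(per_chrom))
}

#' Genome aggregates of a per-chromosome block summary
#'
#' Works from the per-chromosome table alone, so published summary tables can
#' be aggregated as well as freshly computed ones. Two kinds of mean block
#' span are reported, both in cM: the block-count-weighted mean per genome
#' group (`sum(n_blocks * mean_span) / sum(n_blocks)`) and the unweighted
#' mean of the per-chromosome means, since summary tables in the literature
#' print either.
#'
#' @param per_chrom data.frame with at least `chrom`, `total_snps`,
#'   `snps_in_blocks`, `tag_snps`, `n_blocks`, `mean_span_cM`, `total_haps`.
#' @param genome optional grouping vector for the weighted span means; by
#'   default the chromosome label with leading digits stripped (wheat-style
#'   `1A` -> genome `A`).
#' @return list with `total_snps`, `snps_in_blocks`, `pct_snps_in_blocks`,
#'   `tag_snps`, `pct_tag_snps`, `total_blocks`, `total_haplotypes`,
#'   `mean_haplotypes_per_block`, `mean_span_unweighted_cM`,
#'   `mean_span_weighted_cM` (overall), and `mean_span_weighted_by_genome`
#'   (named vector).
#' @export
aggregate_block_summary <- function(per_chrom,
                                    genome = sub("^[0-9]+", "",
                                                 per_chrom$chrom)) {
  ok <- per_chrom$n_blocks > 0
  w <- per_chrom$n_blocks[ok]
  ms <- per_chrom$mean_span_cM[ok]
  by_genome <- tapply(seq_along(w), genome[ok], function(i)
    sum(w[i] * ms[i]) / sum(w[i]))
  list(total_snps = sum(per_chrom$total_snps),
       snps_in_blocks = sum(per_chrom$snps_in_blocks),
       pct_snps_in_blocks = 100 * sum(per_chrom$snps_in_blocks) /
         sum(per_chrom$total_snps),
       tag_snps = sum(per_chrom$tag_snps),
       pct_tag_snps = 100 * sum(per_chrom$tag_snps) /
         sum(per_chrom$total_snps),
       total_blocks = sum(per_chrom$n_blocks),
       total_haplotypes = sum(per_chrom$total_haps),
       mean_haplotypes_per_block = sum(per_chrom$total_haps) /
         sum(per_chrom$n_blocks),
       mean_span_unweighted_cM = mean(ms),
       mean_span_weighted_cM = sum(w * ms) / sum(w),
       mean_span_weighted_by_genome = unlist(as.list(by_genome)))
}
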