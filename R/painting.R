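#' Paint panel lines against a founder reference
#'
#' For every line and every MAF-filtered SNP at which the founder call is
#' non-missing, the state is `same` when the line carries the founder allele,
#' `different` otherwise, and `missing` for a missing (or heterozygous) call.
#' SNPs where the founder itself is missing are unpaintable: every line is
#' `missing` ("white") there. The conventional display colors are green
#' (same), yellow (different) and white (missing).
#'
#' @param panel a [genotype_panel].
#' @param founder_id line id of the founder reference.
#' @param maf MAF cutoff applied before painting (default 0.05; set 0 to
#'   keep all SNPs).
#' @return object of class `painting`: list with `states` (lines x SNPs
#'   character matrix with values `same` / `different` / `missing`),
#'   `founder`, `snp_ids`, `map` (rows for the painted SNPs), `colors`
#'   (named state -> color map).
#' @export
paint_against_founder <- function(panel, founder_id, maf = 0.05) {
  if (!founder_id %in% panel$line_ids)
    stop(sprintf("founder '%s' is not in the panel", founder_id))
  sub <- if (maf > 0) suppressMessages(filter_maf(panel, maf)) else panel
  g <- hom_calls(sub)
  f <- g[founder_id, ]
  states <- matrix("missing", nrow(g), ncol(g), dimnames = dimnames(g))
  paintable <- !is.na(f)
  same <- sweep(g, 2, f, `==`)
  states[!is.na(same) & same &
           matrix(paintable, nrow(g), ncol(g), byrow = TRUE)] <- "same"
  states[!is.na(same) & !same &
           matrix(paintable, nrow(g), ncol(g), byrow = TRUE)] <- "different"
  structure(list(states = states, founder = founder_id,
                 snp_ids = sub$snp_ids, map = sub$map,
                 colors = c(same = "green", different = "yellow",
                            missing = "white")),
            class = "painting")
}

#' @export
print.painting <- function(x, ...) {
  tab <- table(factor(x$states, levels = names(x$colors)))
  cat(sprintf("painting vs founder '%s': %d lines x %d SNPs\n",
              x$founder, nrow(x$states), ncol(x$states)))
  cat(sprintf("  same %.1f%%, different %.1f%%, missing %.1f%%\n",
              100 * tab["same"] / sum(tab),
              100 * tab["different"] / sum(tab),
              100 * tab["missing"] / sum(tab)))
  invisible(x)
}

#' Long plot-ready painting table
#'
#' @param x a `painting`.
#' @param row.names,optional,... standard [as.data.frame()] arguments
#'   (ignored).
#' @return data.frame with `line`, `snp_id`, `chrom`, `cM`, `state`, `color`,
#'   ordered by (chromosome, cM) then line.
#' @export
as.data.frame.painting <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  df <- data.frame(
    line = rep(rownames(x$states), times = ncol(x$states)),
    snp_id = rep(colnames(x$states), each = nrow(x$states)),
    state = as.vector(x$states))
  df$chrom <- x$map$chrom[match(df$snp_id, x$map$snp_id)]
  df$cM <- x$map$cM[match(df$snp_id, x$map$snp_id)]
  df$color <- unname(x$colors[df$state])
  df <- df[order(df$chrom, df$cM, df$snp_id, df$line),
           c("line", "snp_id", "chrom", "cM", "state", "color")]
  rownames(df) <- NULL
  df
}

#' Block transmission summary against the founder
#'
#' Per line and block: the fraction of member SNPs painted `same`
#' (missing states excluded from the denominator). A block is called
#' founder-type when the fraction reaches `founder_threshold`.
#'
#' @param painting a `painting` from [paint_against_founder()].
#' @param blocks a `block_set`; member SNPs absent from the painting (e.g.
#'   dropped by its MAF filter) are ignored.
#' @param founder_threshold call threshold (default 0.9).
#' @return data.frame with `line`, `block_id`, `n_painted`, `frac_same`,
#'   `founder_type`.
#' @export
block_transmission_summary <- function(painting, blocks,
                                       founder_threshold = 0.9) {
  rows <- list()
  for (b in seq_len(nrow(blocks))) {
    members <- intersect(blocks$snps[[b]], painting$snp_ids)
    if (length(members) == 0) next
    st <- painting$states[, members, drop = FALSE]
    n_same <- rowSums(st == "same")
    n_painted <- rowSums(st != "missing")
    frac <- ifelse(n_painted > 0, n_same / n_painted, NA_real_)
    rows[[b]] <- data.frame(line = rownames(st),
                            block_id = blocks$block_id[b],
                            n_painted = n_painted, frac_same = frac,
                            founder_type = !is.na(frac) &
                              frac >= founder_threshold)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  rownames(out) <- NULL
  out
}
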