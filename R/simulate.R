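#' Scenario configuration for the panel generator
#'
#' Describes a synthetic selfing-crop diversity panel: two (or more)
#' subpopulations of inbred lines with Balding-Nichols differentiation `F`,
#' a genetic map organized into planted haplotype blocks separated by
#' independent singleton SNPs, optional selection sweeps that fix one block
#' haplotype in one subpopulation, and block- or SNP-resident QTL feeding the
#' phenotype generator.
#'
#' Defaults mirror a wheat mini-core-style design: 157 landraces and 88
#' modern cultivars, two chromosomes, four founder haplotypes per block,
#' `F = 0.06` between landraces and modern cultivars, four trial
#' environments, and broad-sense heritability 0.6.
#'
#' Within each planted block the founder haplotype pool is built by
#' sequential single-site mutations on a haplotype tree (each SNP mutates on
#' exactly one branch), so every SNP pair inside a block carries at most
#' three of the four possible gametes and the planted block is a solid spine
#' of LD by construction. Between blocks (and for singleton SNPs) sampling is
#' independent: free recombination.
#'
#' @param seed integer seed; all draws (panel and phenotypes) derive from it.
#' @param n_lines named integer vector: lines per population.
#' @param chromosomes data.frame with `name`, `length_cM`, `n_snps`.
#' @param block_snps integer range of SNPs per planted block.
#' @param gap_snps singleton SNPs between consecutive blocks.
#' @param block_span_cM numeric range of planted block spans (cM).
#' @param gap_cM numeric range of between-block gaps (cM).
#' @param n_haplotypes founder-haplotype pool size per block.
#' @param fst Balding-Nichols differentiation parameter in (0, 1).
#' @param selection `NULL` or data.frame with `population`, `chrom`,
#'   `start_cM`, `end_cM`, `haplotype`: fixes that haplotype index in every
#'   overlapped block for that population.
#' @param qtl `NULL` or data.frame with `type` (`"block"` or `"snp"`),
#'   `chrom`, `cM` (locates the containing block / nearest SNP), `haplotype`
#'   (block QTL: which pool haplotype carries the effect), `effect` (trait
#'   units).
#' @param environments data.frame with `env`, `effect` (fixed additive shift
#'   per environment, trait units).
#' @param grand_mean trait grand mean.
#' @param residual_var residual (within-environment) variance.
#' @param h2 target heritability `var(g) / (var(g) + residual_var)`; the
#'   line-level polygenic variance is scaled so total genetic variance
#'   (QTL + polygenic) hits it.
#' @param within_block_recomb probability that a line's block haplotype is a
#'   single-breakpoint recombinant of two pool haplotypes (default 0).
#' @param polygenic_chroms chromosomes contributing to the polygenic term
#'   (default `NULL`: all). Restricting the background to chromosomes that a
#'   scan does not test gives markers that are truly null: on a chromosome
#'   that also carries background effects, markers tag their block-mates'
#'   effects (proximal contamination) and a scan is expected to be mildly
#'   anticonservative.
#' @param missing_rate per-call missing probability.
#' @param het_rate per-call heterozygous probability (inbred panels: ~0).
#' @param trait trait code for generated phenotypes.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1,
                            n_lines = c(landrace = 157, modern = 88),
                            chromosomes = data.frame(
                              name = c("1A", "1B"),
                              length_cM = c(150, 120),
                              n_snps = c(120, 100)),
                            block_snps = c(4L, 8L),
                            gap_snps = 1L,
                            block_span_cM = c(0.2, 2.5),
                            gap_cM = c(2, 6),
                            n_haplotypes = 4L,
                            fst = 0.06,
                            selection = NULL,
                            qtl = NULL,
                            environments = data.frame(
                              env = c("02LY", "05LY", "06LY", "10SY"),
                              effect = c(0, 1.5, -1, 0.8)),
                            grand_mean = 50,
                            residual_var = 4,
                            h2 = 0.6,
                            within_block_recomb = 0,
                            polygenic_chroms = NULL,
                            missing_rate = 0.02,
                            het_rate = 0,
                            trait = "TKW") {
  if (fst <= 0 || fst >= 1) stop("`fst` must be in (0, 1)")
  if (is.null(names(n_lines))) stop("`n_lines` must be named by population")
  if (n_haplotypes < 2) stop("need at least 2 founder haplotypes per block")
  if (min(block_snps) < max(2L, n_haplotypes - 1L))
    stop("blocks need at least max(2, n_haplotypes - 1) SNPs")
  if (h2 < 0 || h2 >= 1) stop("`h2` must be in [0, 1)")
  if (!is.null(selection) && any(selection$haplotype > n_haplotypes))
    stop("selection plan fixes a haplotype index beyond the pool size")
  structure(as.list(environment()), class = "scenario_config")
}

# sample() that never interprets a scalar as 1:x
resample <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Dirichlet draw.
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

# Founder haplotype pool on a perfect phylogeny: k haplotypes over m SNPs,
# each SNP mutating on exactly one branch, so no SNP pair shows 4 gametes.
hap_pool <- function(k, m) {
  stopifnot(m >= k - 1)
  edges <- 2:k
  site_edge <- c(resample(edges),
                 resample(edges, m - (k - 1), replace = TRUE))
  site_edge <- site_edge[sample.int(m)]
  pool <- matrix(0L, k, m)
  parent <- c(NA, vapply(2:k, function(t)
    if (t == 2) 1L else sample.int(t - 1L, 1), integer(1)))
  for (t in 2:k) {
    pool[t, ] <- pool[parent[t], ]
    pool[t, site_edge == t] <- 1L - pool[t, site_edge == t]
  }
  pool
}

#' Simulate a structured inbred panel with planted haplotype blocks
#'
#' Draws the panel described by a [scenario_config()]: ancestral block
#' haplotype frequencies from a Dirichlet, per-population frequencies from
#' the multi-allelic Balding-Nichols model
#' `Dirichlet(p_ancestral (1 - F) / F)`, lines as independent
#' haploid-equivalent mosaics of block haplotypes (free recombination between
#' blocks, none within unless `within_block_recomb > 0`), singleton SNPs
#' drawn independently per line, then the selection plan overwriting the
#' named intervals, and finally missing/heterozygous masking.
#'
#' @param config a [scenario_config()].
#' @return list with `panel` ([genotype_panel]), `partition`
#'   ([population_partition]) and `truth` (planted boundaries, haplotype
#'   pools, ancestral and per-population frequencies, true pre-masking
#'   assignments and calls, selection/QTL bookkeeping, `F`).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  pops <- names(config$n_lines)
  line_ids <- unlist(lapply(pops, function(p)
    sprintf("%s_%03d", p, seq_len(config$n_lines[[p]]))))
  partition <- population_partition(
    stats::setNames(rep(pops, config$n_lines), line_ids))
  n <- length(line_ids)

  map_rows <- list()
  blocks <- list()
  snp_counter <- 0L
  calls <- NULL
  assignments <- list()

  for (ci in seq_len(nrow(config$chromosomes))) {
    chr <- config$chromosomes$name[ci]
    n_snps <- config$chromosomes$n_snps[ci]
    # lay out blocks and gap singletons along a cM walk, then rescale
    pos <- numeric(0)
    snp_block <- integer(0)   # 0 = singleton, b = block index on chromosome
    cursor <- 0
    b <- 0L
    while (length(pos) < n_snps) {
      b <- b + 1L
      m <- resample(seq(config$block_snps[1], config$block_snps[2]), 1)
      m <- min(m, n_snps - length(pos))
      if (m >= max(2L, config$n_haplotypes - 1L)) {
        span <- stats::runif(1, config$block_span_cM[1],
                             config$block_span_cM[2])
        p <- cursor + sort(stats::runif(m, 0, span))
        pos <- c(pos, p)
        snp_block <- c(snp_block, rep(b, m))
        cursor <- max(p)
      } else {
        # tail too short for a block: emit singletons
        for (i in seq_len(m)) {
          cursor <- cursor + stats::runif(1, config$gap_cM[1],
                                          config$gap_cM[2])
          pos <- c(pos, cursor)
          snp_block <- c(snp_block, 0L)
        }
      }
      if (length(pos) < n_snps) {
        for (i in seq_len(config$gap_snps)) {
          if (length(pos) >= n_snps) break
          cursor <- cursor + stats::runif(1, config$gap_cM[1],
                                          config$gap_cM[2]) / 2
          pos <- c(pos, cursor)
          snp_block <- c(snp_block, 0L)
        }
        cursor <- cursor + stats::runif(1, config$gap_cM[1],
                                        config$gap_cM[2]) / 2
      }
    }
    pos <- round(pos / max(pos) * config$chromosomes$length_cM[ci], 3)
    snp_ids <- sprintf("%s_S%04d", chr, snp_counter + seq_along(pos))
    snp_counter <- snp_counter + length(pos)
    map_rows[[chr]] <- data.frame(snp_id = snp_ids, chrom = chr, cM = pos)

    chr_calls <- matrix(NA_integer_, n, length(pos),
                        dimnames = list(line_ids, snp_ids))
    for (bi in setdiff(unique(snp_block), 0L)) {
      members <- which(snp_block == bi)
      k <- config$n_haplotypes
      pool <- hap_pool(k, length(members))
      p_anc <- rdirichlet1(rep(1.5, k))
      p_pop <- lapply(pops, function(p)
        rdirichlet1(p_anc * (1 - config$fst) / config$fst))
      names(p_pop) <- pops
      a <- unlist(lapply(pops, function(p)
        sample.int(k, config$n_lines[[p]], replace = TRUE,
                   prob = p_pop[[p]])))
      names(a) <- line_ids
      geno <- pool[a, , drop = FALSE]
      if (config$within_block_recomb > 0) {
        rec <- which(stats::runif(n) < config$within_block_recomb)
        for (i in rec) {
          other <- sample.int(k, 1)
          bp <- sample.int(length(members) - 1, 1)
          geno[i, (bp + 1):length(members)] <-
            pool[other, (bp + 1):length(members)]
          a[i] <- NA_integer_  # recombinant: no single pool assignment
        }
      }
      chr_calls[, members] <- geno
      blocks[[length(blocks) + 1]] <- list(
        chrom = chr, index = bi, snp_ids = snp_ids[members],
        start_cM = pos[members[1]], end_cM = pos[members[length(members)]],
        pool = pool, p_ancestral = p_anc, p_pop = p_pop)
      assignments[[length(assignments) + 1]] <- a
    }
    singles <- which(snp_block == 0L)
    for (s in singles) {
      p_anc <- stats::runif(1, 0.2, 0.8)
      p_pop <- vapply(pops, function(p)
        stats::rbeta(1, p_anc * (1 - config$fst) / config$fst,
                     (1 - p_anc) * (1 - config$fst) / config$fst),
        numeric(1))
      chr_calls[, s] <- unlist(lapply(seq_along(pops), function(pi)
        stats::rbinom(config$n_lines[[pi]], 1, p_pop[pi])))
    }
    calls <- if (is.null(calls)) chr_calls else cbind(calls, chr_calls)
  }

  truth_blocks <- data.frame(
    block = seq_along(blocks),
    chrom = vapply(blocks, `[[`, character(1), "chrom"),
    start_cM = vapply(blocks, `[[`, numeric(1), "start_cM"),
    end_cM = vapply(blocks, `[[`, numeric(1), "end_cM"),
    n_snps = vapply(blocks, function(b) length(b$snp_ids), integer(1)))
  truth_blocks$snp_ids <- I(lapply(blocks, `[[`, "snp_ids"))
  assign_mat <- do.call(cbind, assignments)
  colnames(assign_mat) <- as.character(seq_along(blocks))

  # selection plan: fix the named haplotype in overlapped blocks
  if (!is.null(config$selection)) {
    for (r in seq_len(nrow(config$selection))) {
      sel <- config$selection[r, ]
      hit <- which(truth_blocks$chrom == sel$chrom &
                     truth_blocks$start_cM <= sel$end_cM &
                     truth_blocks$end_cM >= sel$start_cM)
      sel_lines <- line_ids[unname(partition) == sel$population]
      if (length(sel_lines) == 0)
        stop(sprintf("selection plan names unknown population '%s'",
                     sel$population))
      for (bi in hit) {
        pool <- blocks[[bi]]$pool
        calls[sel_lines, blocks[[bi]]$snp_ids] <-
          matrix(pool[sel$haplotype, ], length(sel_lines),
                 ncol(pool), byrow = TRUE)
        assign_mat[sel_lines, bi] <- as.integer(sel$haplotype)
      }
    }
  }

  true_calls <- calls
  mask <- matrix(stats::runif(length(calls)) < config$missing_rate,
                 nrow(calls))
  calls[mask] <- NA_integer_
  if (config$het_rate > 0) {
    hmask <- matrix(stats::runif(length(calls)) < config$het_rate,
                    nrow(calls)) & !is.na(calls)
    calls[hmask] <- 2L
  }

  map <- do.call(rbind, c(map_rows, make.row.names = FALSE))
  panel <- genotype_panel(calls, map)
  truth <- list(blocks = truth_blocks, pools = lapply(blocks, `[[`, "pool"),
                p_ancestral = lapply(blocks, `[[`, "p_ancestral"),
                p_pop = lapply(blocks, `[[`, "p_pop"),
                assignments = assign_mat, true_calls = true_calls,
                F = config$fst, selection = config$selection,
                config = config)
  list(panel = panel, partition = partition, truth = truth)
}

#' Simulate multi-environment phenotypes on a generated panel
#'
#' `value = grand mean + environment effect + QTL effects + polygenic + e`,
#' with the QTL effects read from the truth record's pre-masking haplotype
#' assignments (block QTL: lines carrying the named pool haplotype) or true
#' allele dosage (SNP QTL), a line-level polygenic term built from small
#' effects across all SNPs and rescaled so total genetic variance hits the
#' target heritability, and iid residuals per (line, environment).
#'
#' @param sim output of [simulate_panel()] (list with `panel`, `truth`).
#' @param config the same [scenario_config()]; its `qtl`, `environments`,
#'   `grand_mean`, `residual_var`, `h2`, `trait` fields drive the phenotype.
#' @return list with `phenotypes` (a [phenotype_table]) and `truth_effects`
#'   (per-line genetic values, the QTL bookkeeping, polygenic variance used,
#'   realized heritability).
#' @export
simulate_phenotypes <- function(sim, config = sim$truth$config) {
  set.seed(config$seed + 1L)
  panel <- sim$panel
  truth <- sim$truth
  n <- n_lines(panel)
  lines <- panel$line_ids

  qtl_contrib <- rep(0, n)
  names(qtl_contrib) <- lines
  qtl_book <- NULL
  if (!is.null(config$qtl)) {
    qtl_book <- config$qtl
    qtl_book$locus <- NA_character_
    for (r in seq_len(nrow(config$qtl))) {
      q <- config$qtl[r, ]
      if (q$type == "block") {
        hit <- which(truth$blocks$chrom == q$chrom &
                       truth$blocks$start_cM <= q$cM &
                       truth$blocks$end_cM >= q$cM)
        if (length(hit) == 0)
          stop(sprintf("no planted block contains %s:%g cM", q$chrom, q$cM))
        hit <- hit[1]
        if (q$haplotype > nrow(truth$pools[[hit]]))
          stop("QTL names a haplotype beyond the pool size")
        carrier <- !is.na(truth$assignments[, hit]) &
          truth$assignments[, hit] == q$haplotype
        qtl_contrib <- qtl_contrib + q$effect * as.numeric(carrier)
        qtl_book$locus[r] <- sprintf("block %d", hit)
      } else {
        on_chr <- panel$map$chrom == q$chrom
        idx <- which(on_chr)[which.min(abs(panel$map$cM[on_chr] - q$cM))]
        snp <- panel$map$snp_id[idx]
        qtl_contrib <- qtl_contrib +
          q$effect * truth$true_calls[lines, snp]
        qtl_book$locus[r] <- snp
      }
    }
  }

  poly_cols <- if (is.null(config$polygenic_chroms)) panel$snp_ids else
    panel$map$snp_id[panel$map$chrom %in% config$polygenic_chroms]
  u <- stats::rnorm(length(poly_cols))
  g <- drop(truth$true_calls[, poly_cols, drop = FALSE] %*% u)
  g <- g - mean(g)
  v_target <- config$residual_var * config$h2 / (1 - config$h2)
  v_qtl <- stats::var(qtl_contrib)
  v_poly <- max(0, v_target - v_qtl)
  g <- if (stats::var(g) > 0 && v_poly > 0)
    g * sqrt(v_poly / stats::var(g)) else rep(0, n)

  genetic <- qtl_contrib + g
  envs <- config$environments
  recs <- do.call(rbind, lapply(seq_len(nrow(envs)), function(e)
    data.frame(line = lines, trait = config$trait, env = envs$env[e],
               value = config$grand_mean + envs$effect[e] + genetic +
                 stats::rnorm(n, sd = sqrt(config$residual_var)))))
  realized_h2 <- stats::var(genetic) /
    (stats::var(genetic) + config$residual_var)
  list(phenotypes = phenotype_table(recs),
       truth_effects = list(genetic_value = stats::setNames(genetic, lines),
                            qtl = qtl_book, polygenic_var = v_poly,
                            realized_h2 = realized_h2))
}

#' Small example panel
#'
#' A compact generated panel (two populations, one chromosome) used in
#' documentation examples.
#'
#' @param seed seed passed to [scenario_config()].
#' @return a [genotype_panel].
#' @export
sim_panel_small <- function(seed = 42) {
  cfg <- scenario_config(
    seed = seed, n_lines = c(landrace = 40, modern = 30),
    chromosomes = data.frame(name = "1A", length_cM = 60, n_snps = 40))
  simulate_panel(cfg)$panel
}
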