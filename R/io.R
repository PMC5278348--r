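#' Read a genotype panel from disk
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`tsv`}{genotype table whose header row holds SNP ids and whose
#'     first column holds line ids; calls are allele symbols, `H` for a
#'     heterozygote, and `NA`, `-` or empty for missing. Requires a side map
#'     file (`map`) with columns `snp_id`, `chrom`, `cM`.}
#'   \item{`hapmap`}{HapMap-style text: columns `rs#`, `alleles` (e.g. `A/B`),
#'     `chrom`, `pos` (taken as cM), then one column per line. `N` is missing,
#'     `H` heterozygous. The standard 11-column header (strand .. QCcode) is
#'     also accepted.}
#'   \item{`vcf`}{VCF with GT fields; `0/0`, `1/1`, `0/1`, `./.` map to the
#'     two homozygous states, heterozygous, and missing. Because VCF POS is in
#'     base pairs, genetic positions come from the side map file (`map`).}
#' }
#'
#' @param path genotype file.
#' @param format one of `"tsv"`, `"hapmap"`, `"vcf"`.
#' @param map path to a tab-delimited map file with columns `snp_id`,
#'   `chrom` (or `chromosome`), `cM`; required for `tsv` and `vcf`.
#' @return a [genotype_panel], SNPs sorted by (chromosome, cM, snp_id).
#' @export
load_genotypes <- function(path, format = c("tsv", "hapmap", "vcf"),
                           map = NULL) {
  format <- match.arg(format)
  switch(format,
         tsv = read_genotypes_tsv(path, map),
         hapmap = read_genotypes_hapmap(path),
         vcf = read_genotypes_vcf(path, map))
}

read_map_file <- function(path) {
  m <- utils::read.delim(path, check.names = FALSE,
                         colClasses = "character")
  names(m)[names(m) == "chromosome"] <- "chrom"
  if (!all(c("snp_id", "chrom", "cM") %in% names(m)))
    stop("map file needs columns snp_id, chrom (or chromosome), cM")
  m$cM <- as.numeric(m$cM)
  if (all(c("allele0", "allele1") %in% names(m)))
    m$allele1[!is.na(m$allele1) & m$allele1 == "."] <- NA_character_
  m
}

# Turn a character call matrix (allele symbols, "H", NA) into integer codes
# plus a per-SNP allele table. `alleles` may pre-specify symbols (hapmap/vcf).
encode_calls <- function(sym, alleles = NULL) {
  miss <- c("NA", "-", "", "N", "./.", ".")
  sym[sym %in% miss] <- NA_character_
  codes <- matrix(NA_integer_, nrow(sym), ncol(sym), dimnames = dimnames(sym))
  if (is.null(alleles)) {
    alleles <- matrix(NA_character_, ncol(sym), 2,
                      dimnames = list(colnames(sym), c("allele0", "allele1")))
    for (j in seq_len(ncol(sym))) {
      obs <- sort(unique(sym[, j][!is.na(sym[, j]) & sym[, j] != "H"]))
      if (length(obs) > 2) {
        bad <- which(!(sym[, j] %in% c(obs[1:2], "H", NA)))[1]
        stop(sprintf("unknown allele symbol '%s' at line '%s', SNP '%s'",
                     sym[bad, j], rownames(sym)[bad], colnames(sym)[j]))
      }
      alleles[j, seq_along(obs)] <- obs
    }
  }
  for (j in seq_len(ncol(sym))) {
    v <- sym[, j]
    code <- rep(NA_integer_, length(v))
    code[v == alleles[j, 1]] <- 0L
    code[!is.na(alleles[j, 2]) & v == alleles[j, 2]] <- 1L
    code[v == "H"] <- 2L
    unknown <- which(!is.na(v) & is.na(code))
    if (length(unknown) > 0)
      stop(sprintf("unknown allele symbol '%s' at line '%s', SNP '%s'",
                   v[unknown[1]], rownames(sym)[unknown[1]], colnames(sym)[j]))
    codes[, j] <- code
  }
  list(codes = codes, alleles = alleles)
}

read_genotypes_tsv <- function(path, map) {
  if (is.null(map)) stop("tsv format requires a `map` file")
  g <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  lines <- g[[1]]
  sym <- as.matrix(g[, -1, drop = FALSE])
  rownames(sym) <- lines
  mp <- read_map_file(map)
  alleles <- NULL
  if (all(c("allele0", "allele1") %in% names(mp))) {
    # allele orientation carried by the map file (written by
    # write_genotypes) so codes round-trip exactly
    alleles <- cbind(allele0 = mp$allele0, allele1 = mp$allele1)
    rownames(alleles) <- mp$snp_id
    alleles <- alleles[colnames(sym), , drop = FALSE]
  }
  enc <- encode_calls(sym, alleles)
  genotype_panel(enc$codes, mp, enc$alleles)
}

read_genotypes_hapmap <- function(path) {
  h <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(h) >= 11 && identical(tolower(names(h)[5]), "strand")) {
    meta <- h[, 1:11]
    lines_cols <- h[, -(1:11), drop = FALSE]
  } else {
    meta <- h[, 1:4]
    lines_cols <- h[, -(1:4), drop = FALSE]
  }
  snp_ids <- meta[[1]]
  al <- strsplit(meta[[2]], "/", fixed = TRUE)
  alleles <- t(vapply(al, function(a) {
    a <- a[a != "." & a != ""]
    c(a, NA_character_)[1:2]
  }, character(2)))
  dimnames(alleles) <- list(snp_ids, c("allele0", "allele1"))
  sym <- t(as.matrix(lines_cols))
  colnames(sym) <- snp_ids
  enc <- encode_calls(sym, alleles)
  map <- data.frame(snp_id = snp_ids, chrom = meta[[3]],
                    cM = as.numeric(meta[[4]]))
  genotype_panel(enc$codes, map, enc$alleles)
}

read_genotypes_vcf <- function(path, map) {
  if (is.null(map)) stop("vcf format requires a `map` file for cM positions")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- vcfR::getID(v)
  if (anyNA(ids)) stop("every VCF record needs an ID for map lookup")
  rownames(gt) <- ids
  alleles <- cbind(allele0 = vcfR::getREF(v), allele1 = vcfR::getALT(v))
  rownames(alleles) <- ids
  code1 <- gsub("|", "/", gt, fixed = TRUE)
  codes <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  codes[code1 == "0/0"] <- 0L
  codes[code1 == "1/1"] <- 1L
  codes[code1 %in% c("0/1", "1/0")] <- 2L
  unknown <- !is.na(code1) & code1 != "./." & is.na(codes)
  if (any(unknown)) {
    idx <- which(unknown)[1]
    stop(sprintf("unsupported GT '%s' at SNP '%s', line '%s'",
                 code1[idx], rownames(gt)[(idx - 1) %% nrow(gt) + 1],
                 colnames(gt)[(idx - 1) %/% nrow(gt) + 1]))
  }
  genotype_panel(t(codes), read_map_file(map), alleles)
}

#' Write a genotype panel to disk
#'
#' Writes the `tsv` dialect (genotype table plus side map file) or a
#' HapMap-style file (map embedded). Reading a written file back reproduces
#' calls, alleles, map and ordering exactly.
#'
#' @param panel a [genotype_panel].
#' @param path output genotype file.
#' @param format `"tsv"` or `"hapmap"`.
#' @param map output map file path (required for `tsv`).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path, format = c("tsv", "hapmap"),
                            map = NULL) {
  format <- match.arg(format)
  sym <- decode_calls(panel,
                      missing_symbol = if (format == "hapmap") "N" else "NA")
  if (format == "tsv") {
    if (is.null(map)) stop("tsv format requires a `map` output path")
    df <- data.frame(line = panel$line_ids, sym, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    mp <- cbind(panel$map,
                allele0 = panel$alleles[, 1],
                allele1 = ifelse(is.na(panel$alleles[, 2]), ".",
                                 panel$alleles[, 2]))
    utils::write.table(mp, map, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    al <- paste(panel$alleles[, 1],
                ifelse(is.na(panel$alleles[, 2]), ".", panel$alleles[, 2]),
                sep = "/")
    df <- data.frame(`rs#` = panel$snp_ids, alleles = al,
                     chrom = panel$map$chrom, pos = panel$map$cM,
                     t(sym), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

decode_calls <- function(panel, missing_symbol = "NA") {
  sym <- matrix(missing_symbol, nrow(panel$calls), ncol(panel$calls),
                dimnames = dimnames(panel$calls))
  for (j in seq_len(ncol(sym))) {
    v <- panel$calls[, j]
    sym[!is.na(v) & v == 0L, j] <- panel$alleles[j, 1]
    if (!is.na(panel$alleles[j, 2]))
      sym[!is.na(v) & v == 1L, j] <- panel$alleles[j, 2]
    sym[!is.na(v) & v == 2L, j] <- "H"
  }
  sym
}

#' Read a long-format phenotype table
#'
#' Tab-delimited file with columns `line`, `trait`, `env`, `value`.
#'
#' @param path file path.
#' @return a [phenotype_table].
#' @export
read_phenotypes <- function(path) {
  phenotype_table(utils::read.delim(path, check.names = FALSE))
}

#' Read population labels
#'
#' Tab-delimited file with columns `line` and `population`.
#'
#' @param path file path.
#' @param panel optional [genotype_panel] for validation.
#' @return a [population_partition].
#' @export
read_populations <- function(path, panel = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (!all(c("line", "population") %in% names(df)))
    stop("population file needs columns line, population")
  population_partition(stats::setNames(df$population, df$line), panel)
}
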