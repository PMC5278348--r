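test_that("tsv and hapmap files round-trip calls, map and ordering exactly", {
  calls <- rbind(L1 = c(0L, 1L, 2L, NA, 0L),
                 L2 = c(1L, 1L, 0L, 0L, 0L),
                 L3 = c(0L, NA, 1L, 1L, 0L))
  colnames(calls) <- paste0("S", 1:5)
  map <- data.frame(snp_id = paste0("S", 1:5),
                    chrom = c("1A", "1A", "1A", "1B", "1B"),
                    cM = c(0, 2.25, 2.25, 1.5, 7.75))
  alleles <- cbind(c("A", "C", "G", "T", "A"), c("B", "T", "A", "C", NA))
  rownames(alleles) <- paste0("S", 1:5)
  p <- genotype_panel(calls, map, alleles)

  for (fmt in c("tsv", "hapmap")) {
    gf <- tempfile(fileext = ".txt")
    mf <- tempfile(fileext = ".map")
    write_genotypes(p, gf, format = fmt, map = mf)
    p2 <- load_genotypes(gf, format = fmt,
                         map = if (fmt == "tsv") mf else NULL)
    expect_identical(p2$calls, p$calls, label = fmt)
    expect_identical(p2$map, p$map)
    expect_identical(p2$snp_ids, p$snp_ids)
    expect_identical(unname(p2$alleles), unname(p$alleles))
  }
})

test_that("panel is sorted by (chromosome, cM, snp id) with ties by id", {
  p <- panel_from_codes(matrix(0L, 2, 4), cM = c(5, 1, 1, 3),
                        snp_ids = c("Sd", "Sc", "Sa", "Sb"))
  expect_identical(p$snp_ids, c("Sa", "Sc", "Sb", "Sd"))
  expect_true(all(diff(p$map$cM) >= 0))
})

test_that("vcf GT fields map onto the four call states", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "L1", "L2", sep = "\t"),
           paste("chr1", "100", "S1", "A", "G", ".", ".", ".", "GT",
                 "0/0", "1/1", sep = "\t"),
           paste("chr1", "200", "S2", "C", "T", ".", ".", ".", "GT",
                 "0/1", "./.", sep = "\t"))
  vf <- tempfile(fileext = ".vcf")
  writeLines(vcf, vf)
  mf <- tempfile()
  writeLines(c("snp_id\tchrom\tcM", "S1\t1A\t0.5", "S2\t1A\t3.1"), mf)
  p <- load_genotypes(vf, format = "vcf", map = mf)
  expect_identical(p$calls["L1", "S1"], 0L)    # 0/0 -> first allele
  expect_identical(p$calls["L2", "S1"], 1L)    # 1/1 -> second allele
  expect_identical(p$calls["L1", "S2"], 2L)    # 0/1 -> heterozygous
  expect_true(is.na(p$calls["L2", "S2"]))      # ./. -> missing
  expect_identical(unname(p$alleles["S1", ]), c("A", "G"))
  expect_equal(p$map$cM, c(0.5, 3.1))
})

test_that("malformed inputs fail with coordinates in the message", {
  calls <- matrix(0L, 2, 2, dimnames = list(c("L1", "L2"), c("S1", "S2")))
  # SNP mapped to two chromosomes
  map2 <- data.frame(snp_id = c("S1", "S1", "S2"),
                     chrom = c("1A", "1B", "1A"), cM = c(0, 1, 2))
  expect_error(genotype_panel(calls, map2), "more than one chromosome")
  # duplicate SNP id in the matrix
  dup <- cbind(calls, S1 = c(0L, 0L))
  expect_error(
    genotype_panel(dup, data.frame(snp_id = c("S1", "S2"), chrom = "1A",
                                   cM = 0:1)),
    "duplicate SNP id 'S1'")
  # unmapped SNP
  expect_error(
    genotype_panel(calls, data.frame(snp_id = "S1", chrom = "1A", cM = 0)),
    "'S2' has no map position")
  # unknown (third) allele symbol in a TSV
  gf <- tempfile(); mf <- tempfile()
  writeLines(c("line\tS1", "L1\tA", "L2\tB", "L3\tX"), gf)
  writeLines(c("snp_id\tchrom\tcM", "S1\t1A\t0"), mf)
  expect_error(load_genotypes(gf, "tsv", map = mf),
               "unknown allele symbol 'X' at line 'L3', SNP 'S1'")
})

test_that("minor allele frequency follows the haploid-inbred convention", {
  # columns: monomorphic, balanced, 1/4 among non-missing, het+missing only
  codes <- cbind(c(0L, 0L, 0L, 0L, 0L),
                 c(0L, 0L, 1L, 1L, NA),
                 c(0L, 0L, 0L, 1L, NA),
                 c(2L, 2L, NA, NA, NA))
  p <- panel_from_codes(codes)
  maf <- minor_allele_frequency(p)
  expect_equal(unname(maf), c(0, 0.5, 0.25, NA))
  # invariant to allele-label swap
  sw <- codes
  sw[] <- ifelse(codes %in% c(0L, 1L), 1L - codes, codes)
  expect_equal(unname(minor_allele_frequency(panel_from_codes(sw))),
               unname(maf))
})

test_that("filter_maf keeps the right SNPs, is idempotent, errors when empty", {
  # MAFs 0, 0.04 (1/25), 0.08 (2/25), 0.32 (8/25)
  n <- 25
  mk <- function(k) c(rep(1L, k), rep(0L, n - k))
  p <- panel_from_codes(cbind(mk(0), mk(1), mk(2), mk(8)))
  expect_equal(
    suppressMessages(n_snps(filter_maf(p, 0.05))), 2)
  expect_identical(filter_maf(p, 0)$calls, p$calls)
  f1 <- suppressMessages(filter_maf(p, 0.05))
  expect_identical(suppressMessages(filter_maf(f1, 0.05))$calls, f1$calls)
  mono <- panel_from_codes(cbind(mk(0), mk(0)))
  expect_error(filter_maf(mono, 0.05), "no SNP passes")
})

test_that("phenotype table rejects duplicate records, partition checks lines", {
  df <- data.frame(line = c("L1", "L1"), trait = "TKW", env = "02LY",
                   value = c(40, 41))
  expect_error(phenotype_table(df), "duplicate record")
  p <- panel_from_codes(matrix(0L, 2, 2))
  expect_error(population_partition(c(L99 = "landrace"), p),
               "not in the panel")
  expect_s3_class(population_partition(c(L01 = "a", L02 = "b"), p),
                  "population_partition")
})
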