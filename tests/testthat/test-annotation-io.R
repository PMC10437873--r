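test_that("site metadata parses fields, missing values and sample types", {
  path <- write_lines_tmp(c(
    "abbrev\tsample_name\tsite_name\tregion\tlat\tlong\tprovince\ttemp\tpH",
    "AA01\tAA0101F\tSpring A\tRegion\t1.5\t-80.2\tPanama slab window\t31.8\t7.5",
    "AA02\tAA0202S\tSpring B\tRegion\t1.6\t-80.3\tPanama slab window\tNM\t",
    "AA03\tAA0303\tSpring C\tRegion\t1.7\t-80.4\tIceland spreading center\t93.5\t2.7"
  ))
  md <- read_site_metadata(path)
  expect_equal(nrow(md), 3L)
  expect_equal(md$temperature, c(31.8, NA, 93.5))
  expect_equal(md$pH, c(7.5, NA, 2.7))
  expect_equal(md$sample_type, c("fluid", "sediment", NA))

  # header-only file -> empty
  empty <- read_site_metadata(write_lines_tmp(
    "abbrev\tsample_name\tsite_name\tregion\tlat\tlong\tprovince\ttemp\tpH"))
  expect_equal(nrow(empty), 0L)

  # malformed numerics are an error naming the row
  bad <- write_lines_tmp(c(
    "abbrev\tsample_name\tsite_name\tregion\tlat\tlong\tprovince\ttemp\tpH",
    "AA01\tAA0101F\tSpring A\tRegion\t1.5\t-80.2\tP\tthirty\t7.5"))
  expect_error(read_site_metadata(bad), "row 1")

  # out-of-range values rejected
  hot <- write_lines_tmp(c(
    "abbrev\tsample_name\tsite_name\tregion\tlat\tlong\tprovince\ttemp\tpH",
    "AA01\tAA0101F\tSpring A\tRegion\t1.5\t-80.2\tP\t150\t7.5"))
  expect_error(read_site_metadata(hot), "temperature")
})

test_that("packaged spring table has the curated values and round-trips", {
  sites <- spring_sites()
  expect_equal(nrow(sites), 63L)
  ao19 <- sites[sites$abbrev == "AO19", ]
  expect_equal(ao19$temperature, 27.8)
  expect_equal(ao19$pH, 6.3)
  expect_equal(ao19$province, "Argentina backarc")
  # NM entries parse as missing, never imputed
  expect_true(is.na(sites$temperature[sites$abbrev == "AR17"]))

  tmp <- tempfile(fileext = ".tsv")
  write_site_metadata(sites, tmp)
  expect_equal(read_site_metadata(tmp), sites)
})

test_that("CAZyme overview parsing: tool support, truncation, order", {
  path <- write_lines_tmp(c(
    "Gene ID\tEC#\tHMMER\teCAMI\tDIAMOND\t#ofTools",
    "c1_001\t-\tGH23(31-186)\t-\tGH23\t2",
    "c1_002\t-\tGH13_20(5-99)\t-\t-\t1",
    "c1_003\t-\t-\t-\tCBM50\t1",
    "c1_004\t-\tGH5_4(1-50)+CBM2(60-99)\tGH5\tGH5\t3",
    "c1_005\t-\t-\t-\t-\t0"
  ))
  ann <- read_cazyme_overview(path)
  expect_equal(ann$gene_id, c("c1_001", "c1_002", "c1_003", "c1_004", "c1_004"))
  # agreement case: one label, both callers
  expect_equal(ann$label[1], "GH23")
  expect_equal(ann$tool_support[1], "HMMER;DIAMOND")
  # subfamily truncation with single-tool support
  expect_equal(ann$label[2], "GH13")
  expect_equal(ann$tool_support[2], "HMMER")
  # multi-domain call contributes both families with full support recorded
  expect_setequal(ann$label[ann$gene_id == "c1_004"], c("GH5", "CBM2"))
  expect_equal(unique(ann$tool_support[ann$gene_id == "c1_004"]),
               "HMMER;eCAMI;DIAMOND")

  expect_error(read_cazyme_overview(write_lines_tmp(c("foo\tHMMER", "x\tGH1"))),
               "gene")
})

test_that("DRAM-style tables yield one record per gene, scheme and label", {
  path <- write_lines_tmp(c(
    "gene_id\tpeptidase_family\tec_number",
    "g1\tM23\tEC 3.4.21.107",
    "g2\t\t",
    "g3\tS11;C26\t",
    "g4\t\t3.1.3.1;2.7.1.1",
    "g5\tM23A\t",
    "g6\tM38\tEC 3.5.1.28",
    "g7\tC44\t",
    "g8\t\tEC 3.4.21.62"
  ))
  ann <- read_dram_annotations(path)
  expect_equal(nrow(ann), 11L)  # counted by hand from the rows above
  expect_equal(sum(ann$scheme == "MEROPS"), 6L)
  expect_equal(sum(ann$scheme == "EC"), 5L)
  g1 <- ann[ann$gene_id == "g1", ]
  expect_setequal(g1$label, c("M23", "3.4.21.107"))
  expect_equal(nrow(ann[ann$gene_id == "g2", ]), 0L)
  # subfamily letter truncated to the family
  expect_equal(ann$label[ann$gene_id == "g5"], "M23")
})

test_that("secretion flag readers give set semantics", {
  expect_equal(read_secretion_flags(write_lines_tmp("gene_id\tprediction")),
               character(0))
  path <- write_lines_tmp(c("gene_id\tprediction", "g1\tSP(Sec/SPI)",
                            "g2\tOTHER", "g3\tSP(Sec/SPI)", "g4\tOTHER",
                            "g5\tSP(Sec/SPI)", "g5\tSP(Sec/SPI)"))
  flags <- read_secretion_flags(path)
  expect_setequal(flags, c("g1", "g3", "g5"))
  expect_equal(length(flags), 3L)  # duplicates collapse
})

test_that("GFF3 gene maps resolve IDs to contigs and skip FASTA sections", {
  genes <- data.frame(gene_id = c("ctg1_001", "ctg1_002", "ctg2_001"),
                      contig_id = c("ctg1", "ctg1", "ctg2"),
                      start = c(1, 101, 1), end = c(90, 190, 90), strand = "+")
  path <- tempfile(fileext = ".gff")
  write_gene_map(genes, path, fasta = c(ctg1 = "ACGTACGT"))
  map <- read_gene_map(path)
  expect_equal(map[["ctg1_002"]], "ctg1")
  expect_equal(unname(map[genes$gene_id]), genes$contig_id)

  dup <- tempfile(fileext = ".gff")
  writeLines(c("##gff-version 3",
               "ctgA\tx\tCDS\t1\t90\t.\t+\t0\tID=g1",
               "ctgB\tx\tCDS\t1\t90\t.\t+\t0\tID=g1"), dup)
  expect_error(read_gene_map(dup), "multiple contigs")
})

test_that("generated GFF maps agree with the generator's own gene placement", {
  study <- generate_study(small_config(), tempfile("gff"))
  sid <- study$truth$samples$sample_id[1L]
  map <- read_gene_map(study$files[[sid]][["gff"]])
  expect_true(length(map) >= 20L)
  # prokka convention: gene id prefix (up to the last underscore) is the contig
  expect_equal(unname(map), sub("_[^_]*$", "", names(map)))
})

test_that("coverage readers handle both dialects and reject bad depth", {
  path <- write_lines_tmp(c("contig_id\tmean_depth\tlength",
                            "c1\t10.5\t2000", "c2\t0\t1500"))
  cov <- read_coverage(path)
  expect_equal(cov$mean_depth, c(10.5, 0))  # zero-coverage contig retained
  tmp <- tempfile(); write_coverage(cov, tmp)
  expect_equal(read_coverage(tmp), cov)

  expect_error(read_coverage(write_lines_tmp(
    c("contig_id\tmean_depth\tlength", "c1\t-2\t100"))), ">= 0")

  # per-base dialect aggregates to the brute-force mean
  per_base <- c(sprintf("cA\t%d\t%d", 1:4, c(2, 4, 6, 8)),
                sprintf("cB\t%d\t%d", 1:3, c(5, 5, 5)))
  agg <- read_coverage(write_lines_tmp(per_base), format = "per_base")
  expect_equal(agg$mean_depth[agg$contig_id == "cA"], mean(c(2, 4, 6, 8)))
  expect_equal(agg$length[agg$contig_id == "cB"], 3)
})

test_that("assembly stats require positive totals", {
  ok <- read_assembly_stats(write_lines_tmp(
    c("sample_id\ttotal_length\tn_contigs", "s1\t5645364\t912")))
  expect_equal(ok$total_length, 5645364)
  expect_error(read_assembly_stats(write_lines_tmp(
    c("sample_id\ttotal_length\tn_contigs", "s1\t0\t10"))), "> 0")
})

test_that("readers are total on every file the generator writes", {
  study <- generate_study(small_config(), tempfile("total"))
  inputs <- read_study_files(study$files)
  expect_s3_class(inputs$annots, "data.frame")
  expect_true(nrow(inputs$annots) > 0)
  expect_true(all(inputs$annots$scheme %in% c("CAZY", "MEROPS", "EC")))
  expect_equal(nrow(inputs$assembly_stats), 3L)
})
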