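make_annots <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], contig_id = NA_character_, scheme = r[[2]],
               label = r[[3]], tool_support = r[[4]],
               secreted = r[[5]], sample_id = r[[6]], stringsAsFactors = FALSE)))
}

test_that("annotation gating applies secretion, two-tool and EC-class rules", {
  ann <- make_annots(
    list("g1", "CAZY", "GH23", "HMMER;DIAMOND", TRUE, "s1"),
    list("g2", "CAZY", "GH23", "HMMER", TRUE, "s1"),          # one tool
    list("g3", "CAZY", "GH23", "HMMER;eCAMI", TRUE, "s1"),    # eCAMI no help
    list("g4", "CAZY", "GH23", "HMMER;DIAMOND", FALSE, "s1"), # not secreted
    list("g5", "MEROPS", "M23", "DRAM", TRUE, "s1"),          # single annotator ok
    list("g6", "EC", "2.7.1.1", "DRAM", TRUE, "s1"),          # not a hydrolase
    list("g7", "EC", "3.1.3.1", "DRAM", TRUE, "s1")
  )
  out <- filter_annotations(ann)
  expect_setequal(out$gene_id, c("g1", "g5", "g7"))
  # switches relax individual rules
  expect_true("g4" %in% filter_annotations(ann, secreted_only = FALSE)$gene_id)
  expect_true("g2" %in% filter_annotations(ann, min_two_tools = FALSE)$gene_id)
  expect_true("g6" %in% filter_annotations(ann, ec_hydrolases_only = FALSE)$gene_id)
})

test_that("per-gene abundance is the host contig's mean depth", {
  cov <- data.frame(contig_id = c("cA", "cB"), mean_depth = c(10, 0),
                    length = c(2000, 3000))
  map <- c(g1 = "cA", g2 = "cA", g3 = "cB")
  expect_equal(gene_abundance("g1", map, cov), 10)
  # two genes on one contig each contribute the full depth
  expect_equal(sum(gene_abundance(c("g1", "g2"), map, cov)), 20)
  expect_equal(gene_abundance("g3", map, cov), 0)
  # prokka fallback: prefix up to the last underscore
  expect_equal(gene_abundance("cB_017", character(0), cov), 0)
  expect_error(gene_abundance("orphan", map, cov), "orphan")
})

test_that("matrix construction normalizes depth by assembly size", {
  ann <- make_annots(list("cA_001", "CAZY", "GH23", "HMMER;DIAMOND", TRUE, "s1"))
  cov <- data.frame(contig_id = "cA", mean_depth = 10, length = 5000)
  stats <- data.frame(sample_id = "s1", total_length = 1e6, n_contigs = 1)
  m <- build_matrix(ann, character(0), cov, stats, "CAZY")
  expect_equal(unname(m["GH23", "s1"]), 10 * 1e9 / 1e6)  # = 10,000

  # linearity in depth
  cov2 <- cov; cov2$mean_depth <- cov2$mean_depth * 2
  m2 <- build_matrix(ann, character(0), cov2, stats, "CAZY")
  expect_equal(unclass(m2), unclass(m) * 2)

  # a sample with no passing annotations keeps an all-zero column
  stats2 <- rbind(stats, data.frame(sample_id = "s2", total_length = 2e6,
                                    n_contigs = 1))
  m3 <- build_matrix(ann, character(0), cov, stats2, "CAZY")
  expect_equal(colnames(m3), c("s1", "s2"))
  expect_equal(unname(m3[, "s2"]), 0)

  expect_error(build_matrix(ann, character(0), cov,
                            data.frame(sample_id = "sX", total_length = 1e6,
                                       n_contigs = 1), "CAZY"),
               "assembly statistics")
})

test_that("matrix accumulation equals brute-force per-gene summation", {
  study <- generate_study(small_config(), tempfile("brute"))
  inputs <- read_study_files(study$files)
  fl <- filter_annotations(inputs$annots)
  fl50 <- fl[seq_len(min(50L, nrow(fl))), , drop = FALSE]  # 50-gene fixture
  m <- build_matrix(fl50, inputs$gene_map, inputs$coverage,
                    inputs$assembly_stats, "CAZY")
  oracle <- brute_force_matrix(fl50, inputs$gene_map, inputs$coverage,
                               inputs$assembly_stats, "CAZY")
  expect_equal(unclass(m), oracle, tolerance = 1e-12,
               ignore_attr = c("scheme", "normalization"))
  # column sums match the brute-force totals too
  expect_equal(colSums(m), colSums(oracle), tolerance = 1e-12)
})

test_that("prevalence filter keeps families above the ceiling threshold", {
  m <- matrix(c(1, 1, 1, 1,   # in 4/4
                2, 3, 0, 0,   # in 2/4 = 50%
                1, 1, 1, 0,   # in 3/4 = 75%
                0, 0, 0, 0),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("GH1", "GH2", "GH3", "GH4"), paste0("s", 1:4)))
  kept <- rownames(prevalence_filter(m, 0.75))
  expect_setequal(kept, c("GH1", "GH3"))
  # min_frac = 0 keeps everything nonzero somewhere
  expect_setequal(rownames(prevalence_filter(m, 0)), c("GH1", "GH2", "GH3"))
  expect_error(prevalence_filter(m, 1.5), "min_frac")
})

test_that("raising the prevalence threshold never adds a family", {
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(rbinom(60, 1, 0.5) * runif(60), nrow = 10,
                dimnames = list(paste0("F", 1:10), paste0("s", 1:6)))
    fams <- lapply(c(0, 0.25, 0.5, 0.75, 1), function(f)
      rownames(prevalence_filter(m, f)))
    for (i in seq_len(length(fams) - 1L))
      expect_true(all(fams[[i + 1L]] %in% fams[[i]]))
  }
})

test_that("display transform is entrywise log10(x + 0.5)", {
  m <- matrix(c(0, 0.5, 99.5, 2), 2, 2)
  tr <- viz_transform(m)
  expect_equal(tr[1, 1], log10(0.5), tolerance = 1e-10)
  expect_equal(tr[2, 1], 0)
  expect_equal(tr[1, 2], 2)
  expect_error(viz_transform(matrix(-1)), ">= 0")
})

test_that("abundance matrices round-trip through TSV + sidecar", {
  ann <- make_annots(list("cA_001", "CAZY", "GH23", "HMMER;DIAMOND", TRUE, "s1"),
                     list("cA_002", "CAZY", "GH5", "HMMER;DIAMOND", TRUE, "s1"))
  cov <- data.frame(contig_id = "cA", mean_depth = 4, length = 5000)
  stats <- data.frame(sample_id = "s1", total_length = 1e6, n_contigs = 1)
  m <- build_matrix(ann, character(0), cov, stats, "CAZY")
  tmp <- tempfile(fileext = ".tsv")
  write_abundance_matrix(m, tmp)
  m2 <- read_abundance_matrix(tmp)
  expect_equal(unclass(m2), unclass(m))
  expect_equal(attr(m2, "scheme"), "CAZY")
})

test_that("uniform depth rescaling of one sample leaves its fraction unchanged", {
  study <- generate_study(small_config(), tempfile("scale"))
  inputs <- read_study_files(study$files)
  fl <- filter_annotations(inputs$annots)
  map <- substrate_group_map()
  meta <- metadata_by_sample(inputs$metadata, inputs$assembly_stats$sample_id)
  base <- score_table(build_matrix(fl, inputs$gene_map, inputs$coverage,
                                   inputs$assembly_stats, "CAZY"),
                      map, meta)

  sid <- inputs$assembly_stats$sample_id[1L]
  cov2 <- inputs$coverage
  scaled <- startsWith(cov2$contig_id, sid)
  cov2$mean_depth[scaled] <- cov2$mean_depth[scaled] * 37.5
  rescaled <- score_table(build_matrix(fl, inputs$gene_map, cov2,
                                       inputs$assembly_stats, "CAZY"),
                          map, meta)
  f1 <- base$necromass_fraction[base$sample_id == sid]
  f2 <- rescaled$necromass_fraction[rescaled$sample_id == sid]
  expect_equal(f1, f2, tolerance = 1e-12)
})
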