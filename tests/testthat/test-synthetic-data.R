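test_that("configuration validation names the offending field", {
  expect_error(simulation_config(cell_vs_photo_ratio = 1.5),
               "cell_vs_photo_ratio")
  expect_error(simulation_config(secreted_prob = -0.1), "secreted_prob")
  expect_error(simulation_config(hightemp_depauperation = 0),
               "hightemp_depauperation")
  expect_error(simulation_config(volcanic_cellulose_enrichment = 0.5),
               "volcanic_cellulose_enrichment")
  expect_error(simulation_config(n_sites = 0), "n_sites")
  expect_error(simulation_config(scheme_probs = c(CAZY = 1, MEROPS = 1, EC = 0)),
               "scheme_probs")
})

test_that("identical configurations yield byte-identical file sets", {
  cfg <- simulation_config(n_sites = 4, seed = 7)
  d1 <- tempfile("det1"); d2 <- tempfile("det2")
  generate_study(cfg, d1)
  generate_study(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_equal(h1, h2)
})

test_that("simulation configs round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_sites = 5, cell_vs_photo_ratio = 0.6, seed = 3,
                        depth_dist = list(shape = 2, rate = 0.5)), path)
  cfg <- read_simulation_config(path)
  expect_equal(cfg$n_sites, 5L)
  expect_equal(cfg$cell_vs_photo_ratio, 0.6)
  expect_equal(unname(cfg$depth_dist), c(2, 0.5))
  # CLI-style seed override
  expect_equal(read_simulation_config(path, seed = 42)$seed, 42L)
})

test_that("high-temperature depauperation thins annotations as planted", {
  hotcold <- data.frame(
    province = c("cold", "hot"), prob = c(0.5, 0.5),
    volcanic = FALSE,
    temp_min = c(30, 85), temp_max = c(40, 95),
    ph_min = 6, ph_max = 8, stringsAsFactors = FALSE)
  base <- list(n_sites = 8, provinces = hotcold, n_contigs_per_sample = 60,
               genes_per_contig = 10, seed = 19)
  full <- do.call(simulation_config,
                  c(base, list(hightemp_depauperation = 1)))
  thin <- do.call(simulation_config,
                  c(base, list(hightemp_depauperation = 0.1)))
  st_full <- generate_study(full, tempfile("full"))
  st_thin <- generate_study(thin, tempfile("thin"))
  # same seed, so both runs share sample assignments and candidate tables
  expect_equal(st_full$truth$samples$temperature,
               st_thin$truth$samples$temperature)
  hot <- st_full$truth$samples$sample_id[st_full$truth$samples$temperature > 80]
  cold <- setdiff(st_full$truth$samples$sample_id, hot)
  expect_gt(length(hot), 0); expect_gt(length(cold), 0)

  # cold samples are untouched by the thinning
  for (sid in cold)
    expect_equal(count_annotation_rows(st_thin, sid),
                 count_annotation_rows(st_full, sid))

  # retained hot rows ~ Binomial(candidates, 0.1); brute-force 99.9% CI
  n_candidates <- sum(vapply(hot, function(s) count_annotation_rows(st_full, s),
                             numeric(1)))
  n_kept <- sum(vapply(hot, function(s) count_annotation_rows(st_thin, s),
                       numeric(1)))
  ci <- qbinom(c(5e-4, 1 - 5e-4), n_candidates, 0.1)
  expect_gte(n_kept, ci[1L])
  expect_lte(n_kept, ci[2L])
})

test_that("stronger depauperation never increases hot-sample annotations", {
  hotonly <- data.frame(province = "hot", prob = 1, volcanic = FALSE,
                        temp_min = 85, temp_max = 95, ph_min = 6, ph_max = 8,
                        stringsAsFactors = FALSE)
  counts <- vapply(c(0.05, 0.2, 0.6, 1), function(d) {
    cfg <- simulation_config(n_sites = 2, provinces = hotonly,
                             n_contigs_per_sample = 40, genes_per_contig = 8,
                             hightemp_depauperation = d, seed = 23)
    st <- generate_study(cfg, tempfile("mono"))
    sum(vapply(st$truth$samples$sample_id,
               function(s) count_annotation_rows(st, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("planted necromass fraction is recovered exactly without noise", {
  # all genes grouped, secreted, two-tool CAZymes on constant-depth contigs:
  # the pipeline sees exactly the planted gene set
  cfg <- noise_free_config(n_sites = 2, n_contigs = 250, genes_per_contig = 20,
                           ratio = 0.7, seed = 101)
  res <- run_pipeline(cfg, tempfile("recov"))
  truth <- res$truth$samples
  got <- res$scores$necromass_fraction[match(truth$sample_id,
                                             res$scores$sample_id)]
  expect_equal(got, truth$true_necromass_fraction, tolerance = 1e-10)
  # ~5000 genes per sample pin the realized fraction near the target
  expect_true(all(abs(got - 0.7) <= 0.02))
})

test_that("volcanic cellulose enrichment separates provinces in photosynthate PCA", {
  prov <- PROVINCE_DEFAULTS
  prov$temp_max <- pmin(prov$temp_max, 75)   # keep depauperation out of this check
  cfg <- simulation_config(n_sites = 10, provinces = prov,
                           n_contigs_per_sample = 120, genes_per_contig = 12,
                           volcanic_cellulose_enrichment = 6, seed = 31)
  study <- generate_study(cfg, tempfile("pca"))
  inputs <- read_study_files(study$files)
  fl <- filter_annotations(inputs$annots)
  m <- build_matrix(fl, inputs$gene_map, inputs$coverage,
                    inputs$assembly_stats, "CAZY")
  map <- substrate_group_map()
  volcanic <- study$truth$samples$volcanic
  expect_gt(length(unique(volcanic)), 1L)  # seed fixed: both classes drawn

  silhouette1d <- function(scores, grp) {
    # mean silhouette on PC1 distances, brute force
    d <- as.matrix(dist(scores))
    mean(vapply(seq_along(grp), function(i) {
      a <- mean(d[i, grp == grp[i] & seq_along(grp) != i])
      b <- mean(d[i, grp != grp[i]])
      (b - a) / max(a, b)
    }, numeric(1)))
  }
  photo_f <- intersect(supergroup_families(map, "photosynthate", "CAZY",
                                           "exclusive"), rownames(m))
  p_photo <- pca_profiles(m[photo_f, , drop = FALSE])
  s_photo <- silhouette1d(p_photo$scores[, 1, drop = FALSE], volcanic)
  expect_gt(s_photo, 0)

  cell_f <- intersect(supergroup_families(map, "cell", "CAZY", "exclusive"),
                      rownames(m))
  p_cell <- pca_profiles(m[cell_f, , drop = FALSE])
  s_cell <- silhouette1d(p_cell$scores[, 1, drop = FALSE], volcanic)
  # cell families carry no planted province signal; photosynthate separates better
  expect_gt(s_photo, s_cell)
})

test_that("noisy assay plates recover the true rate on average", {
  cal <- calibration(slope = 100, intercept = 500)
  true_rate <- 0.02
  rec <- vapply(1:100, function(i) {
    p <- generate_assay_plate(c(BG = true_rate), cal, noise_sd = 5, seed = 1000 + i)
    hydrolysis_rate(p$BG, cal)$rate
  }, numeric(1))
  sem <- sd(rec) / sqrt(length(rec))
  expect_lte(abs(mean(rec) - true_rate), 2 * sem + 1e-12)
})
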