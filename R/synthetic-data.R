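# Synthetic study generator: writes a complete file set (site metadata,
# CAZyme overview tables, DRAM-style annotation tables, signal-peptide
# summaries, GFF3 gene maps, contig coverage, assembly statistics) with
# planted province/temperature structure, and returns the planted truth so
# every downstream stage can be checked against ground truth. Only
# annotation-level tables are generated - no reads or sequences.

#' Default geological province table for the synthetic generator
#'
#' Seven provinces spanning the surveyed convergent margins and spreading
#' center, with uniform assignment probabilities, a volcanic flag, and
#' temperature/pH ranges at the observed extremes of the curated site
#' table. Used as the `provinces` default of [simulation_config()].
#'
#' @format data frame with columns `province`, `prob`, `volcanic`,
#'   `temp_min`, `temp_max`, `ph_min`, `ph_max`.
#' @export
PROVINCE_DEFAULTS <- data.frame(
  province = c("Costa Rica outer forearc", "Costa Rica active volcanic arc",
               "Costa Rica backarc", "Cordillera Talamanca",
               "Panama slab window", "Argentina backarc",
               "Iceland spreading center"),
  prob = rep(1 / 7, 7),
  volcanic = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
  temp_min = c(26.4, 19.2, 28.7, 26.0, 26.3, 27.8, 25.7),
  temp_max = c(48.7, 88.9, 35.0, 60.0, 50.9, 84.0, 93.5),
  ph_min = c(7.1, 0.8, 5.8, 6.5, 7.0, 3.2, 1.8),
  ph_max = c(9.9, 6.3, 9.5, 9.6, 10.0, 9.1, 2.7),
  stringsAsFactors = FALSE
)

default_family_pools <- function() {
  map <- substrate_group_map()
  cazy <- unique(map$table$family[map$table$scheme == "CAZY"])
  merops_pg <- unique(map$table$family[map$table$scheme == "MEROPS"])
  list(
    CAZY = c(cazy, paste0("GH", 131:150)),          # 20 ungrouped background
    MEROPS = c(merops_pg,
               c("S09", "S33", "M38", "C26", "C44", "S49", "M20", "M50",
                 "S16", "S01", "M01", "C01", "A01", "S08", "M24", "M28",
                 "C40", "S12", "M16", "T01")),
    EC = c("3.4.21.107", "3.5.1.28", "3.4.21.62", "3.4.21.102", "3.4.21.26",
           "3.4.21.63", "3.1.1.3", "3.5.2.6", "3.1.3.1", "3.2.1.21",
           "3.2.1.51", "3.4.14.5", "3.4.15.1", "3.2.1.1",
           "2.7.1.1", "1.1.1.1", "4.2.1.1", "6.3.1.2", "5.3.1.9", "2.3.1.12")
  )
}

#' Configuration for the synthetic study generator
#'
#' All knobs of [generate_study()] with validation. Defaults emulate the
#' surveyed study design: seven geological provinces with
#' temperature/pH ranges at the observed extremes, fluid and sediment
#' samples, a planted cell:photosynthate gene composition, cellulose
#' enrichment at volcanic provinces, and strong annotation depauperation
#' above 80 degC.
#'
#' @param n_sites number of samples to simulate.
#' @param provinces data frame with columns `province`, `prob`
#'   (assignment probabilities), `volcanic`, `temp_min`, `temp_max`,
#'   `ph_min`, `ph_max`.
#' @param frac_fluid proportion of samples that are fluids (rest are
#'   sediments).
#' @param n_contigs_per_sample contigs per assembly.
#' @param contig_length_dist log-normal parameters `c(meanlog, sdlog)` for
#'   contig length in bp.
#' @param genes_per_contig Poisson mean gene count per contig.
#' @param scheme_probs probabilities that a gene is annotated under each
#'   scheme, named `CAZY`, `MEROPS`, `EC` (must sum to 1).
#' @param scheme_family_pools named list of family label pools per scheme;
#'   default: the packaged substrate-group families plus 20 ungrouped
#'   background families per scheme.
#' @param group_gene_prob probability a CAZY gene is drawn from the
#'   substrate-grouped (cell or photosynthate) pools rather than the
#'   background pool.
#' @param cell_vs_photo_ratio target proportion of grouped CAZY genes
#'   drawn from cell-group families, in `[0, 1]`. Grouped genes are drawn
#'   from supergroup-exclusive families so the planted necromass fraction
#'   is exactly this ratio in expectation.
#' @param volcanic_cellulose_enrichment multiplicative weight (>= 1) on
#'   cellulose-exclusive families when drawing photosynthate genes at
#'   volcanic provinces.
#' @param hightemp_depauperation retention probability (0, 1] for
#'   annotation rows of samples hotter than 80 degC.
#' @param secreted_prob probability a gene carries a signal peptide.
#' @param two_tool_prob probability a CAZY annotation is supported by both
#'   HMMER and DIAMOND.
#' @param depth_dist gamma parameters `c(shape, rate)` for contig mean
#'   depth, or `NULL` for noise-free constant depth 10.
#' @param seed random seed (integer).
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_sites = 12,
                              provinces = PROVINCE_DEFAULTS,
                              frac_fluid = 0.5,
                              n_contigs_per_sample = 60,
                              contig_length_dist = c(meanlog = 8.5, sdlog = 1),
                              genes_per_contig = 8,
                              scheme_probs = c(CAZY = 0.35, MEROPS = 0.45, EC = 0.2),
                              scheme_family_pools = default_family_pools(),
                              group_gene_prob = 0.6,
                              cell_vs_photo_ratio = 0.7,
                              volcanic_cellulose_enrichment = 3,
                              hightemp_depauperation = 0.1,
                              secreted_prob = 0.6,
                              two_tool_prob = 0.85,
                              depth_dist = c(shape = 4, rate = 0.4),
                              seed = 1L) {
  check_count(n_sites, "n_sites")
  if (!is.data.frame(provinces) ||
      !all(c("province", "prob", "volcanic", "temp_min", "temp_max",
             "ph_min", "ph_max") %in% names(provinces)))
    stop_field("provinces", "must be a data frame like PROVINCE_DEFAULTS")
  if (any(provinces$prob < 0) || sum(provinces$prob) <= 0)
    stop_field("provinces", "assignment probabilities must be >= 0, not all 0")
  check_prob(frac_fluid, "frac_fluid")
  check_count(n_contigs_per_sample, "n_contigs_per_sample")
  if (length(contig_length_dist) != 2L || any(!is.finite(contig_length_dist)))
    stop_field("contig_length_dist", "must be c(meanlog, sdlog)")
  check_pos(genes_per_contig, "genes_per_contig")
  if (abs(sum(scheme_probs) - 1) > 1e-8 || any(scheme_probs < 0) ||
      !all(c("CAZY", "MEROPS", "EC") %in% names(scheme_probs)))
    stop_field("scheme_probs", "must be named CAZY/MEROPS/EC and sum to 1")
  if (!all(c("CAZY", "MEROPS", "EC") %in% names(scheme_family_pools)))
    stop_field("scheme_family_pools", "needs CAZY, MEROPS and EC pools")
  check_prob(group_gene_prob, "group_gene_prob")
  check_prob(cell_vs_photo_ratio, "cell_vs_photo_ratio")
  if (!is.numeric(volcanic_cellulose_enrichment) ||
      volcanic_cellulose_enrichment < 1)
    stop_field("volcanic_cellulose_enrichment", "must be >= 1")
  if (!is.numeric(hightemp_depauperation) || hightemp_depauperation <= 0 ||
      hightemp_depauperation > 1)
    stop_field("hightemp_depauperation", "must be in (0, 1]")
  check_prob(secreted_prob, "secreted_prob")
  check_prob(two_tool_prob, "two_tool_prob")
  if (!is.null(depth_dist) &&
      (length(depth_dist) != 2L || any(depth_dist <= 0)))
    stop_field("depth_dist", "must be c(shape, rate) > 0, or NULL for constant depth")
  structure(list(n_sites = as.integer(n_sites), provinces = provinces,
                 frac_fluid = frac_fluid,
                 n_contigs_per_sample = as.integer(n_contigs_per_sample),
                 contig_length_dist = contig_length_dist,
                 genes_per_contig = genes_per_contig,
                 scheme_probs = scheme_probs,
                 scheme_family_pools = scheme_family_pools,
                 group_gene_prob = group_gene_prob,
                 cell_vs_photo_ratio = cell_vs_photo_ratio,
                 volcanic_cellulose_enrichment = volcanic_cellulose_enrichment,
                 hightemp_depauperation = hightemp_depauperation,
                 secreted_prob = secreted_prob,
                 two_tool_prob = two_tool_prob,
                 depth_dist = depth_dist, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields override the defaults of [simulation_config()];
#' `provinces` may be given as a list of records.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's value.
#' @return a `simulation_config`.
#' @export
read_simulation_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$provinces))
    raw$provinces <- do.call(rbind, lapply(raw$provinces, as.data.frame))
  if (!is.null(raw$scheme_probs)) raw$scheme_probs <- unlist(raw$scheme_probs)
  if (!is.null(raw$contig_length_dist))
    raw$contig_length_dist <- unlist(raw$contig_length_dist)
  if (!is.null(raw$depth_dist)) raw$depth_dist <- unlist(raw$depth_dist)
  if (!is.null(seed)) raw$seed <- seed
  do.call(simulation_config, raw)
}

# grouped-family pools: supergroup-exclusive CAZy families, so that the
# planted cell:photosynthate ratio is exactly recoverable under the
# count-once-per-supergroup rule (shared families would add to both sums)
planting_pools <- function(config) {
  map <- substrate_group_map()
  pool <- config$scheme_family_pools$CAZY
  cell <- intersect(supergroup_families(map, "cell", "CAZY", "exclusive"), pool)
  photo <- intersect(supergroup_families(map, "photosynthate", "CAZY", "exclusive"),
                     pool)
  cellulose <- unique(map$table$family[map$table$group == "cellulose" &
                                         map$table$scheme == "CAZY"])
  xylan <- unique(map$table$family[map$table$group == "xylan" &
                                     map$table$scheme == "CAZY"])
  list(cell = cell, photo = photo,
       photo_cellulose_only = setdiff(intersect(photo, cellulose), xylan),
       background = setdiff(pool, c(cell, photo,
                                    unique(map$table$family[map$table$scheme == "CAZY"]))))
}

#' Generate a complete synthetic study file set
#'
#' Simulates `config$n_sites` spring samples: metadata (province,
#' temperature, pH, fluid/sediment type), contigs with log-normal lengths
#' and gamma (or constant) mean depths, Poisson gene counts per contig,
#' and per-gene annotations under the CAZY/MEROPS/EC schemes with planted
#' structure: a fixed cell:photosynthate composition among grouped CAZy
#' genes, cellulose-family enrichment at volcanic provinces, Bernoulli
#' signal peptides and HMMER+DIAMOND support, and thinned annotation
#' tables for samples hotter than 80 degC. Writes the same file dialects
#' the package's readers consume and returns the planted truth.
#'
#' Identical config (including seed) reproduces byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list of class `synthetic_study`: `dir`, `files`
#'   (named paths), `truth` (per-sample planted cell/photosynthate
#'   abundance and necromass fraction; province composition weights) and
#'   `config`.
#' @export
generate_study <- function(config, outdir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  prov <- config$provinces
  pools <- planting_pools(config)
  if (config$group_gene_prob > 0 &&
      (length(pools$cell) == 0L || length(pools$photo) == 0L))
    stop_field("scheme_family_pools",
               "CAZY pool must contain cell- and photosynthate-exclusive families")

  n <- config$n_sites
  pidx <- sample.int(nrow(prov), n, replace = TRUE,
                     prob = prov$prob / sum(prov$prob))
  type <- ifelse(runif(n) < config$frac_fluid, "F", "S")
  sample_ids <- sprintf("SYN%02d%s", seq_len(n), type)
  temperature <- round(runif(n, prov$temp_min[pidx], prov$temp_max[pidx]), 1)
  pH <- round(runif(n, prov$ph_min[pidx], prov$ph_max[pidx]), 2)

  meta <- data.frame(
    abbrev = sprintf("SYN%02d", seq_len(n)),
    sample_name = sample_ids,
    site_name = sprintf("Synthetic spring %02d", seq_len(n)),
    region = "Synthetic",
    latitude = round(runif(n, -30, 65), 5),
    longitude = round(runif(n, -90, -20), 5),
    province = prov$province[pidx],
    temperature = temperature,
    pH = pH,
    stringsAsFactors = FALSE
  )
  meta_path <- file.path(outdir, "sites.tsv")
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NM")

  files <- list(sites = meta_path)
  stats_rows <- vector("list", n)
  truth_rows <- vector("list", n)

  for (i in seq_len(n)) {
    sid <- sample_ids[i]
    volcanic <- prov$volcanic[pidx[i]]
    nc <- config$n_contigs_per_sample
    contig_id <- sprintf("%s_c%04d", sid, seq_len(nc))
    contig_len <- pmax(1500L, as.integer(round(rlnorm(
      nc, config$contig_length_dist[[1L]], config$contig_length_dist[[2L]]))))
    depth <- if (is.null(config$depth_dist)) rep(10, nc) else
      rgamma(nc, shape = config$depth_dist[[1L]], rate = config$depth_dist[[2L]])
    depth <- round(depth, 4)
    ngenes <- rpois(nc, config$genes_per_contig)
    total_genes <- sum(ngenes)

    gene_contig_idx <- rep(seq_len(nc), ngenes)
    gene_id <- sprintf("%s_%03d", contig_id[gene_contig_idx],
                       sequence(ngenes))

    scheme <- sample(names(config$scheme_probs), total_genes, replace = TRUE,
                     prob = config$scheme_probs)
    label <- character(total_genes)
    planted <- character(total_genes)   # "", "cell", "photo"

    is_cazy <- scheme == "CAZY"
    grouped <- is_cazy & runif(total_genes) < config$group_gene_prob
    is_cell <- grouped & runif(total_genes) < config$cell_vs_photo_ratio
    is_photo <- grouped & !is_cell
    planted[is_cell] <- "cell"
    planted[is_photo] <- "photo"
    label[is_cell] <- sample(pools$cell, sum(is_cell), replace = TRUE)
    if (any(is_photo)) {
      w <- rep(1, length(pools$photo))
      if (volcanic)
        w[pools$photo %in% pools$photo_cellulose_only] <-
          config$volcanic_cellulose_enrichment
      label[is_photo] <- sample(pools$photo, sum(is_photo), replace = TRUE,
                                prob = w)
    }
    bg <- is_cazy & !grouped
    if (any(bg)) {
      bg_pool <- if (length(pools$background)) pools$background else
        config$scheme_family_pools$CAZY
      label[bg] <- sample(bg_pool, sum(bg), replace = TRUE)
    }
    is_mer <- scheme == "MEROPS"
    label[is_mer] <- sample(config$scheme_family_pools$MEROPS, sum(is_mer),
                            replace = TRUE)
    is_ec <- scheme == "EC"
    label[is_ec] <- sample(config$scheme_family_pools$EC, sum(is_ec),
                           replace = TRUE)

    secreted <- runif(total_genes) < config$secreted_prob
    two_tool <- runif(total_genes) < config$two_tool_prob
    single_tool <- ifelse(runif(total_genes) < 0.5, "HMMER", "DIAMOND")
    has_ecami <- runif(total_genes) < 0.3
    subfam <- runif(total_genes) < 0.2         # dbcan subfamily suffix on HMMER call
    # always drawn so the RNG stream is identical across depauperation values
    u_keep <- runif(total_genes)
    keep <- temperature[i] <= 80 | u_keep < config$hightemp_depauperation

    gene_depth <- depth[gene_contig_idx]
    total_length <- sum(contig_len)

    # planted truth: normalized abundance of planted genes, pre-filter
    truth_cell <- sum(gene_depth[planted == "cell"]) * 1e9 / total_length
    truth_photo <- sum(gene_depth[planted == "photo"]) * 1e9 / total_length
    truth_rows[[i]] <- data.frame(
      sample_id = sid, province = prov$province[pidx[i]], volcanic = volcanic,
      temperature = temperature[i], pH = pH[i],
      sample_type = ifelse(type[i] == "F", "fluid", "sediment"),
      true_cell = truth_cell, true_photo = truth_photo,
      true_necromass_fraction = necromass_fraction(truth_cell, truth_photo),
      stringsAsFactors = FALSE
    )

    # CAZy overview (dbcan dialect)
    ci <- which(is_cazy & keep)
    hmmer_call <- ifelse(subfam[ci],
                         sprintf("%s_%d(34-%d)", label[ci],
                                 1L + (seq_along(ci) %% 9L), 150L),
                         sprintf("%s(34-150)", label[ci]))
    has_hmmer <- two_tool[ci] | single_tool[ci] == "HMMER"
    has_diamond <- two_tool[ci] | single_tool[ci] == "DIAMOND"
    overview <- data.frame(
      `Gene ID` = gene_id[ci],
      `EC#` = "-",
      HMMER = ifelse(has_hmmer, hmmer_call, "-"),
      eCAMI = ifelse(has_ecami[ci], label[ci], "-"),
      DIAMOND = ifelse(has_diamond, label[ci], "-"),
      `#ofTools` = has_hmmer + has_diamond + has_ecami[ci],
      check.names = FALSE, stringsAsFactors = FALSE
    )
    p_overview <- file.path(outdir, sprintf("%s_cazy_overview.tsv", sid))
    write.table(overview, p_overview, sep = "\t", quote = FALSE,
                row.names = FALSE)

    # DRAM-style table (MEROPS + EC)
    di <- which((is_mer | is_ec) & keep)
    dram <- data.frame(
      gene_id = gene_id[di],
      peptidase_family = ifelse(is_mer[di], label[di], ""),
      ec_number = ifelse(is_ec[di], paste0("EC ", label[di]), ""),
      stringsAsFactors = FALSE
    )
    p_dram <- file.path(outdir, sprintf("%s_annotations.tsv", sid))
    write.table(dram, p_dram, sep = "\t", quote = FALSE, row.names = FALSE)

    # signal peptide summary over all genes
    sp <- data.frame(gene_id = gene_id,
                     prediction = ifelse(secreted, "SP(Sec/SPI)", "OTHER"),
                     stringsAsFactors = FALSE)
    p_sp <- file.path(outdir, sprintf("%s_signalp.tsv", sid))
    write.table(sp, p_sp, sep = "\t", quote = FALSE, row.names = FALSE)

    # GFF3 gene map (with a token FASTA section, which readers must skip)
    starts <- unlist(lapply(ngenes, function(k) seq_len(max(k, 0L)) * 100L - 99L),
                     use.names = FALSE)
    genes_df <- data.frame(gene_id = gene_id, contig_id = contig_id[gene_contig_idx],
                           start = starts, end = starts + 89L, strand = "+",
                           stringsAsFactors = FALSE)
    p_gff <- file.path(outdir, sprintf("%s_genes.gff", sid))
    write_gene_map(genes_df, p_gff,
                   fasta = setNames("ACGTACGTACGT", contig_id[1L]))

    cov <- data.frame(contig_id = contig_id, mean_depth = depth,
                      length = contig_len, stringsAsFactors = FALSE)
    p_cov <- file.path(outdir, sprintf("%s_coverage.tsv", sid))
    write_coverage(cov, p_cov)

    stats_rows[[i]] <- data.frame(sample_id = sid, total_length = total_length,
                                  n_contigs = nc, stringsAsFactors = FALSE)
    files[[sid]] <- c(cazy_overview = p_overview, annotations = p_dram,
                      signalp = p_sp, gff = p_gff, coverage = p_cov)
  }

  stats <- do.call(rbind, stats_rows)
  p_stats <- file.path(outdir, "assembly_stats.tsv")
  write.table(stats, p_stats, sep = "\t", quote = FALSE, row.names = FALSE)
  files$assembly_stats <- p_stats

  truth <- do.call(rbind, truth_rows)
  province_weights <- data.frame(
    province = prov$province, volcanic = prov$volcanic,
    prob = prov$prob / sum(prov$prob),
    cellulose_enrichment = ifelse(prov$volcanic,
                                  config$volcanic_cellulose_enrichment, 1),
    stringsAsFactors = FALSE
  )
  invisible(structure(list(dir = outdir, files = files,
                           truth = list(samples = truth,
                                        province_weights = province_weights),
                           config = config),
                      class = "synthetic_study"))
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d samples in %s\n",
              nrow(x$truth$samples), x$dir))
  print(x$truth$samples[, c("sample_id", "province", "temperature",
                            "sample_type", "true_necromass_fraction")],
        digits = 3)
  invisible(x)
}

#' Simulate a fluorometric assay plate with a known hydrolysis rate
#'
#' The forward model inverted by [hydrolysis_rate()]: fluorophore
#' concentration grows linearly at the rate implied by the true hydrolysis
#' rate, the sediment mass per well and the well volume; fluorescence is
#' the calibrated signal plus Gaussian noise.
#'
#' @param true_rates named numeric vector, umol g_wet^-1 h^-1 per
#'   substrate (>= 0; names from `AG, BG, CB, NAG, LEU, PHOS, SULF, XYL`).
#' @param cal a [calibration()].
#' @param noise_sd fluorescence noise standard deviation (>= 0).
#' @param seed optional seed.
#' @param spec a [slurry_spec()].
#' @param timepoints assay timepoints in hours (default 0, 1.5, 3).
#' @param n_replicates duplicate wells per substrate.
#' @param sample_id sample identifier.
#' @return named list of [assay_plate()]s, one per substrate.
#' @export
generate_assay_plate <- function(true_rates, cal, noise_sd = 0, seed = NULL,
                                 spec = slurry_spec(),
                                 timepoints = c(0, 1.5, 3),
                                 n_replicates = 2, sample_id = "SYN01S") {
  if (any(true_rates < 0)) stop("true_rates must be >= 0", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mass <- sediment_mass_per_well(spec)
  vol_l <- well_volume_l(spec)
  out <- lapply(names(true_rates), function(sub) {
    conc <- true_rates[[sub]] * mass * timepoints / vol_l   # uM
    mu <- cal$intercept + cal$slope * conc
    fl <- matrix(rep(mu, each = n_replicates), nrow = n_replicates) +
      matrix(rnorm(n_replicates * length(timepoints), 0, noise_sd),
             nrow = n_replicates)
    fl <- pmax(fl, 0)
    assay_plate(sample_id, sub, timepoints, fl)
  })
  setNames(out, names(true_rates))
}
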