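# End-to-end orchestration: simulate (or take user files), read, filter,
# tabulate, score, ordinate, and emit TSV outputs plus a Markdown report
# whose every number is recomputable from the emitted tables.

#' Assemble per-sample metadata keyed by sample id
#'
#' Site metadata tables carry one row per site; samples are
#' `<abbrev><F|S>`. This helper expands a metadata table into per-sample
#' rows for the given sample ids, matching on the abbreviation prefix when
#' the full sample id is absent.
#'
#' @param metadata data frame from [read_site_metadata()].
#' @param sample_ids character vector of sample ids (ending F/S).
#' @return data frame with columns `sample_id`, `province`, `sample_type`,
#'   `temperature`, `pH`.
#' @export
metadata_by_sample <- function(metadata, sample_ids) {
  key <- if (all(sample_ids %in% metadata$sample_name)) {
    match(sample_ids, metadata$sample_name)
  } else {
    match(sub("[FS]$", "", sample_ids), metadata$abbrev)
  }
  if (anyNA(key))
    stop(sprintf("no metadata for sample(s): %s",
                 paste(sample_ids[is.na(key)], collapse = ", ")), call. = FALSE)
  data.frame(sample_id = sample_ids,
             province = metadata$province[key],
             sample_type = sample_type_from_id(sample_ids),
             temperature = metadata$temperature[key],
             pH = metadata$pH[key],
             stringsAsFactors = FALSE)
}

#' Read a complete study file set
#'
#' Loads every per-sample table of a study laid out as [generate_study()]
#' emits it (named list: `sites`, `assembly_stats`, and per sample a named
#' vector with `cazy_overview`, `annotations`, `signalp`, `gff`,
#' `coverage` paths), joining secretion flags onto the annotations.
#'
#' @param files named list of input paths.
#' @return list with `metadata`, `assembly_stats`, `annots` (all samples,
#'   with `sample_id`), `coverage`, `gene_map`.
#' @export
read_study_files <- function(files) {
  sample_files <- files[!names(files) %in% c("sites", "assembly_stats")]
  annots <- list()
  coverage <- list()
  gene_map <- character(0)
  for (sid in names(sample_files)) {
    f <- sample_files[[sid]]
    ann <- rbind(read_cazyme_overview(f[["cazy_overview"]]),
                 read_dram_annotations(f[["annotations"]]))
    if (nrow(ann)) ann$sample_id <- sid
    ann <- join_secretion_flags(ann, read_secretion_flags(f[["signalp"]]))
    annots[[sid]] <- ann
    coverage[[sid]] <- read_coverage(f[["coverage"]])
    gene_map <- c(gene_map, read_gene_map(f[["gff"]]))
  }
  list(metadata = read_site_metadata(files$sites),
       assembly_stats = read_assembly_stats(files$assembly_stats),
       annots = do.call(rbind, unname(annots)),
       coverage = do.call(rbind, unname(coverage)),
       gene_map = gene_map)
}

#' Run the full analysis pipeline
#'
#' Drives every stage from one configuration: synthetic mode (pass a
#' [simulation_config()]) generates a study first; file mode consumes a
#' named list of input paths in the layout [generate_study()] emits;
#' score-only mode (`list(score_table = path)`) reloads a previously
#' written score table and reports on it. Outputs: per-scheme abundance
#' matrices (TSV + JSON sidecar), the substrate score table, sample
#' dendrogram (Newick), PCA scores for cell- and photosynthate-family
#' submatrices, a Markdown report, and a JSON run manifest with input
#' checksums and stage timings. Every number in the report is recomputable
#' from the emitted TSVs.
#'
#' @param config a `simulation_config`, a list of files, or
#'   `list(score_table = path)`.
#' @param outdir output directory.
#' @param prevalence_min_frac prevalence threshold for the visualization
#'   matrices.
#' @param frac_threshold,photo_share_threshold,hightemp_threshold report
#'   cut-offs: necromass fraction below which a sample counts as
#'   photosynthate-dominated, photosynthate share above which a sample is
#'   flagged, and the degC bound defining "high temperature".
#' @return invisibly, a list with the computed objects (`matrices`,
#'   `scores`, `ordination`, `report_path`, `manifest`).
#' @export
run_pipeline <- function(config, outdir,
                         prevalence_min_frac = 0.75,
                         frac_threshold = 0.5,
                         photo_share_threshold = 0.3,
                         hightemp_threshold = 80) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    tick(name)
    res
  }

  if (!inherits(config, "simulation_config") && !is.null(config$score_table)) {
    return(invisible(score_only_report(config$score_table, outdir,
                                       frac_threshold, photo_share_threshold)))
  }

  seed <- NULL
  if (inherits(config, "simulation_config")) {
    seed <- config$seed
    study <- stage("simulate",
                   generate_study(config, file.path(outdir, "inputs")))
    files <- study$files
  } else {
    study <- NULL
    files <- config$files %||% config
  }

  inputs <- stage("read", read_study_files(files))
  filtered <- stage("filter", filter_annotations(inputs$annots))
  meta <- metadata_by_sample(inputs$metadata, inputs$assembly_stats$sample_id)

  schemes <- intersect(c("CAZY", "MEROPS", "EC"), unique(inputs$annots$scheme))
  matrices <- stage("profile", {
    ms <- lapply(schemes, function(sch)
      build_matrix(filtered, inputs$gene_map, inputs$coverage,
                   inputs$assembly_stats, sch))
    setNames(ms, schemes)
  })
  for (sch in names(matrices))
    write_abundance_matrix(matrices[[sch]],
                           file.path(outdir, sprintf("abundance_%s.tsv", sch)))

  map <- substrate_group_map()
  scores <- stage("score", score_table(matrices, map, meta))
  write_score_table(scores, file.path(outdir, "substrate_scores.tsv"))
  fs <- fluid_sediment_summary(scores)
  write.table(fs$by_group, file.path(outdir, "fluid_sediment_sums.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ordination <- stage("ordinate", {
    res <- list()
    cazy <- matrices[["CAZY"]]
    if (!is.null(cazy) && ncol(cazy) >= 3L) {
      prev <- prevalence_filter(cazy, prevalence_min_frac)
      corr <- spearman_matrix(if (nrow(prev) >= 2L) prev else cazy, "samples")
      if (length(corr$undefined) == 0L) {
        hc <- cluster_profiles(corr)
        write_dendrogram(hc, file.path(outdir, "samples_dendrogram.nwk"))
        res$sample_cluster <- hc
      }
      for (sg in c("cell", "photosynthate")) {
        fams <- intersect(supergroup_families(map, sg, "CAZY"), rownames(cazy))
        if (length(fams) >= 2L) {
          p <- pca_profiles(cazy[fams, , drop = FALSE])
          utils::write.table(
            data.frame(sample_id = rownames(p$scores),
                       round(p$scores[, seq_len(min(3L, ncol(p$scores))),
                                      drop = FALSE], 6)),
            file.path(outdir, sprintf("pca_%s_scores.tsv", sg)),
            sep = "\t", quote = FALSE, row.names = FALSE)
          res[[paste0("pca_", sg)]] <- p
        }
      }
    }
    res
  })

  report_path <- stage("report",
                       write_report(outdir, inputs, filtered, matrices, scores,
                                    fs, ordination, frac_threshold,
                                    photo_share_threshold, hightemp_threshold,
                                    meta))

  manifest <- list(
    package_version = as.character(packageVersion("geothermenz")),
    seed = seed,
    config_hash = hash_object(if (is.null(study)) files else study$config),
    inputs = input_inventory(files),
    stage_timings_s = timings
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(matrices = matrices, scores = scores, ordination = ordination,
                 truth = if (is.null(study)) NULL else study$truth,
                 report_path = report_path, manifest = manifest))
}

hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

input_inventory <- function(files) {
  paths <- unlist(files, use.names = FALSE)
  data.frame(file = basename(paths), md5 = unname(tools::md5sum(paths)),
             stringsAsFactors = FALSE)
}

count_line <- function(label, value) sprintf("- %s: %s", label, value)

write_report <- function(outdir, inputs, filtered, matrices, scores, fs,
                         ordination, frac_threshold, photo_share_threshold,
                         hightemp_threshold, meta) {
  tot <- attr(scores, "totals")
  fr <- scores$necromass_fraction
  hot <- meta$sample_id[!is.na(meta$temperature) &
                          meta$temperature > hightemp_threshold]
  ann_counts <- table(factor(filtered$scheme,
                             levels = names(matrices) %||% unique(filtered$scheme)))
  lines <- c(
    "# Secreted enzyme potential report",
    "",
    "## Annotations (post-filter, per scheme)",
    sprintf("- %s: %d records, %d families", names(ann_counts),
            as.integer(ann_counts),
            vapply(names(ann_counts),
                   function(s) length(unique(filtered$label[filtered$scheme == s])),
                   integer(1))),
    "",
    "## Substrate scores",
    count_line("samples scored", nrow(scores)),
    count_line("total cell-degrading abundance", sprintf("%.2f", tot[["cell"]])),
    count_line("total photosynthate-degrading abundance",
               sprintf("%.2f", tot[["photosynthate"]])),
    count_line(sprintf("samples with necromass fraction < %.2f", frac_threshold),
               sum(fr < frac_threshold, na.rm = TRUE)),
    count_line(sprintf("samples with photosynthate share > %.2f",
                       photo_share_threshold),
               sum((1 - fr) > photo_share_threshold, na.rm = TRUE)),
    count_line("  of which sediments",
               sum((1 - fr) > photo_share_threshold &
                     scores$sample_type == "sediment", na.rm = TRUE)),
    count_line("samples with undefined fraction", sum(is.na(fr))),
    count_line(sprintf("samples above %.0f degC", hightemp_threshold),
               length(hot)),
    "",
    "## Fluid vs sediment totals",
    sprintf("- %s: cell %.2f, photosynthate %.2f", colnames(fs$overall),
            fs$overall["cell", ], fs$overall["photosynthate", ])
  )
  if (length(ordination)) {
    lines <- c(lines, "", "## Ordination")
    if (!is.null(ordination$sample_cluster))
      lines <- c(lines, count_line("sample dendrogram leaves (left to right)",
                                   paste(ordination$sample_cluster$labels[
                                     ordination$sample_cluster$order],
                                     collapse = " ")))
    for (sg in c("cell", "photosynthate")) {
      p <- ordination[[paste0("pca_", sg)]]
      if (!is.null(p))
        lines <- c(lines, count_line(
          sprintf("%s-family PCA variance (PC1, PC2)", sg),
          paste(sprintf("%.3f", p$explained_variance_fraction[1:2]),
                collapse = ", ")))
    }
  }
  path <- file.path(outdir, "report.md")
  writeLines(lines, path)
  path
}

score_only_report <- function(score_path, outdir, frac_threshold,
                              photo_share_threshold) {
  df <- read.delim(score_path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("cell_abundance", "photo_abundance")
  if (!all(need %in% names(df))) {
    # accept the reference layout (site/cell/plant columns)
    alt <- c(cell = "cell", plant = "plant")
    if (all(alt %in% names(df))) {
      df$cell_abundance <- df$cell
      df$photo_abundance <- df$plant
      df$sample_id <- df$site %||% df$sample_id
      df$sample_type <- tolower(df$type %||% NA_character_)
    } else {
      stop(sprintf("%s: not a recognizable score table", score_path),
           call. = FALSE)
    }
  }
  df$necromass_fraction <- necromass_fraction(df$cell_abundance,
                                              df$photo_abundance)
  class(df) <- c("substrate_scores", "data.frame")
  attr(df, "totals") <- c(cell = sum(df$cell_abundance),
                          photosynthate = sum(df$photo_abundance))
  s <- summary(df, frac_threshold, photo_share_threshold)
  lines <- c(
    "# Substrate score report",
    "",
    count_line("samples scored", s$n_samples),
    count_line("total cell-degrading abundance",
               sprintf("%.2f", s$totals[["cell"]])),
    count_line("total photosynthate-degrading abundance",
               sprintf("%.2f", s$totals[["photosynthate"]])),
    count_line(sprintf("samples with necromass fraction < %.2f", frac_threshold),
               s$n_below_threshold),
    count_line(sprintf("samples with photosynthate share > %.2f",
                       photo_share_threshold),
               s$n_high_photo_share),
    count_line("  of which sediments", s$n_high_photo_share_sediment)
  )
  path <- file.path(outdir, "report.md")
  writeLines(lines, path)
  list(scores = df, summary = s, report_path = path)
}
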