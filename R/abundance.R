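# Annotation gating and coverage-normalized family x sample abundance
# matrices. Normalization fixes depth-per-gigabase of assembly:
# value(family, sample) = sum over passing genes of host-contig mean depth
# multiplied by 1e9 / total assembly length. The absolute scale is
# arbitrary; downstream substrate fractions are scale-free.

NORMALIZATION_SCALE <- 1e9

#' Gate annotations on secretion, tool support and EC class
#'
#' Applies the selection rules of the secreted-enzyme workflow: keep only
#' genes predicted to carry a signal peptide; for CAZymes, keep only calls
#' supported by both HMMER and DIAMOND (additional callers count toward
#' `tool_support` but do not satisfy the rule); for EC annotations, keep
#' only class 3 (hydrolases). MEROPS and EC schemes come from a single
#' annotator, so the two-tool rule applies to CAZY only.
#'
#' @param annots annotation data frame (see [read_cazyme_overview()]) with
#'   a logical `secreted` column already joined (see
#'   [join_secretion_flags()]).
#' @param secreted_only drop genes without a signal peptide (default TRUE).
#' @param min_two_tools require HMMER + DIAMOND support for CAZY rows
#'   (default TRUE).
#' @param ec_hydrolases_only keep only EC labels starting `3.`
#'   (default TRUE).
#' @return the filtered annotation data frame.
#' @export
filter_annotations <- function(annots, secreted_only = TRUE,
                               min_two_tools = TRUE,
                               ec_hydrolases_only = TRUE) {
  keep <- rep(TRUE, nrow(annots))
  if (secreted_only) keep <- keep & !is.na(annots$secreted) & annots$secreted
  if (min_two_tools) {
    tools <- strsplit(annots$tool_support, ";", fixed = TRUE)
    both <- vapply(tools, function(tt) all(c("HMMER", "DIAMOND") %in% tt),
                   logical(1))
    keep <- keep & (annots$scheme != "CAZY" | both)
  }
  if (ec_hydrolases_only)
    keep <- keep & (annots$scheme != "EC" | startsWith(annots$label, "3."))
  annots[keep, , drop = FALSE]
}

#' Join secretion flags onto an annotation table
#'
#' @param annots annotation data frame.
#' @param secreted_ids character vector of secreted gene ids, as returned
#'   by [read_secretion_flags()].
#' @return `annots` with its `secreted` column set.
#' @export
join_secretion_flags <- function(annots, secreted_ids) {
  annots$secreted <- annots$gene_id %in% secreted_ids
  annots
}

resolve_contig <- function(gene_ids, gene_map) {
  contig <- unname(gene_map[gene_ids])
  # prokka convention fallback: gene id is "<contig>_<n>"
  miss <- is.na(contig)
  contig[miss] <- sub("_[^_]*$", "", gene_ids[miss])
  contig
}

#' Per-gene abundance: the mean read depth of the host contig
#'
#' Every annotated gene inherits its contig's mean depth; several genes on
#' one contig each count. Genes absent from the map fall back to the
#' prokka convention (the gene id up to the last `_` is the contig id).
#'
#' @param gene_ids character vector of gene ids.
#' @param gene_map named character vector from [read_gene_map()].
#' @param coverage data frame from [read_coverage()].
#' @return numeric vector of mean depths, one per gene.
#' @export
gene_abundance <- function(gene_ids, gene_map, coverage) {
  contig <- resolve_contig(gene_ids, gene_map)
  idx <- match(contig, coverage$contig_id)
  if (anyNA(idx)) {
    missing <- unique(gene_ids[is.na(idx)])
    stop(sprintf("gene(s) not mappable to a covered contig: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  }
  coverage$mean_depth[idx]
}

#' Build a normalized family-by-sample abundance matrix
#'
#' For one annotation scheme, accumulates per-gene contig depth into
#' family rows and normalizes each sample column by its total assembly
#' length (times 1e9, i.e. depth per gigabase). A gene carrying k family
#' labels contributes to all k families. Samples present in
#' `assembly_stats` but with no passing annotation get an all-zero column.
#'
#' @param annots filtered annotation data frame with a `sample_id` column.
#' @param gene_map named character vector (gene id -> contig id); may be
#'   empty when gene ids follow the prokka `<contig>_<n>` convention.
#' @param coverage contig coverage data frame covering all samples.
#' @param assembly_stats data frame from [read_assembly_stats()]; defines
#'   the sample universe and normalization constants.
#' @param scheme which scheme to tabulate (`"CAZY"`, `"MEROPS"`, `"EC"`).
#' @return an `abundance_matrix`: numeric matrix (families x samples) with
#'   attributes `scheme` and `normalization`.
#' @export
build_matrix <- function(annots, gene_map, coverage, assembly_stats, scheme) {
  if (!"sample_id" %in% names(annots))
    stop("annotations need a 'sample_id' column", call. = FALSE)
  ann <- annots[annots$scheme == scheme, , drop = FALSE]
  missing <- setdiff(unique(ann$sample_id), assembly_stats$sample_id)
  if (length(missing))
    stop(sprintf("no assembly statistics for sample(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  samples <- assembly_stats$sample_id
  families <- sort(unique(ann$label))
  mat <- matrix(0, nrow = length(families), ncol = length(samples),
                dimnames = list(families, samples))
  if (nrow(ann) > 0L) {
    depth <- gene_abundance(ann$gene_id, gene_map, coverage)
    acc <- tapply(depth, list(ann$label, ann$sample_id), sum)
    mat[rownames(acc), colnames(acc)] <- ifelse(is.na(acc), 0, acc)
    total <- assembly_stats$total_length[match(samples, assembly_stats$sample_id)]
    mat <- sweep(mat, 2L, NORMALIZATION_SCALE / total, `*`)
  }
  structure(mat, scheme = scheme,
            normalization = sprintf("depth_x%g_per_bp", NORMALIZATION_SCALE),
            class = c("abundance_matrix", "matrix", "array"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d %s families x %d samples (%s)\n",
              nrow(x), attr(x, "scheme") %||% "?", ncol(x),
              attr(x, "normalization") %||% "unnormalized"))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE], ...)
  if (nrow(x) > 6L || ncol(x) > 6L) cat("...\n")
  invisible(x)
}

#' Drop low-prevalence families from an abundance matrix
#'
#' Retains families detected (abundance strictly positive) in at least
#' `ceiling(min_frac * n_samples)` samples. The survey's figures use
#' `min_frac = 0.75`.
#'
#' @param mat an `abundance_matrix` (or plain matrix).
#' @param min_frac minimum prevalence fraction, in (0, 1].
#' @return the matrix restricted to retained family rows.
#' @export
prevalence_filter <- function(mat, min_frac = 0.75) {
  if (!is.numeric(min_frac) || min_frac < 0 || min_frac > 1)
    stop("min_frac must be in [0, 1]", call. = FALSE)
  need <- max(ceiling(min_frac * ncol(mat)), 1L)
  keep <- rowSums(mat > 0) >= need
  out <- mat[keep, , drop = FALSE]
  attributes(out)[c("scheme", "normalization", "class")] <-
    attributes(mat)[c("scheme", "normalization", "class")]
  out
}

#' Display transform for abundance heatmaps
#'
#' Entrywise `log10(x + 0.5)`; the 0.5 offset avoids zeros. Used for
#' visualization only - rank-based statistics (Spearman) use untransformed
#' abundances.
#'
#' @param mat non-negative abundance matrix.
#' @return transformed matrix with a `transformed` attribute.
#' @export
viz_transform <- function(mat) {
  if (any(mat < 0)) stop("abundances must be >= 0", call. = FALSE)
  out <- log10(mat + 0.5)
  attributes(out)[c("scheme", "normalization", "class")] <-
    attributes(mat)[c("scheme", "normalization", "class")]
  attr(out, "transformed") <- "log10(x + 0.5)"
  out
}

#' Write / read an abundance matrix as TSV with a JSON sidecar
#'
#' The TSV has families as rows and samples as columns; the sidecar
#' `<path>.json` records the scheme and normalization so a matrix can be
#' reloaded without guessing.
#'
#' @param mat an `abundance_matrix`.
#' @param path output TSV path.
#' @return `path` (write) or the matrix (read), invisibly/visibly.
#' @export
write_abundance_matrix <- function(mat, path) {
  df <- data.frame(family = rownames(mat), unclass(mat), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(scheme = attr(mat, "scheme"),
               normalization = attr(mat, "normalization"),
               n_families = nrow(mat), n_samples = ncol(mat))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_abundance_matrix
#' @export
read_abundance_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(mat, scheme = meta$scheme %||% NA_character_,
            normalization = meta$normalization %||% NA_character_,
            class = c("abundance_matrix", "matrix", "array"))
}
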