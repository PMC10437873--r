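# Readers and writers for every external table the pipeline consumes:
# site metadata, dbcan-style CAZyme overviews, DRAM-style peptidase/EC
# annotations, signal-peptide summaries, GFF3 gene maps, contig coverage
# and assembly statistics. Readers are deliberately total on the files the
# synthetic generator writes; writers emit the same dialects.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, na.strings = NULL,
             colClasses = "character", comment.char = "")
}

find_column <- function(df, pattern, path, required = TRUE) {
  hit <- grep(pattern, names(df), ignore.case = TRUE)
  if (length(hit) == 0L) {
    if (required)
      stop(sprintf("%s: no column matching '%s' (found: %s)",
                   path, pattern, paste(names(df), collapse = ", ")),
           call. = FALSE)
    return(NA_integer_)
  }
  hit[1L]
}

parse_numeric_field <- function(x, field, path, missing_tokens = c("", "NA", "NM")) {
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  present <- !(x %in% missing_tokens)
  out[present] <- suppressWarnings(as.numeric(x[present]))
  bad <- present & is.na(out)
  if (any(bad))
    stop(sprintf("%s: malformed numeric value '%s' in column '%s' (row %d)",
                 path, x[which(bad)[1L]], field, which(bad)[1L]), call. = FALSE)
  out
}

# site metadata ---------------------------------------------------------

#' Read a site metadata table
#'
#' Expects a tab-separated table with columns for the site abbreviation,
#' sample name, region, geological province, latitude, longitude,
#' temperature (degC) and pH. `"NM"` (not measured) and empty fields parse
#' as missing; they are never imputed. A trailing `F`/`S` on the sample
#' name sets the fluid/sediment sample type.
#'
#' @param path path to a TSV file with a header row.
#' @return a data frame with columns `abbrev`, `sample_name`, `site_name`,
#'   `region`, `latitude`, `longitude`, `province`, `temperature`, `pH`,
#'   `sample_type`.
#' @seealso [spring_sites()] for the packaged reference table of the 63
#'   surveyed springs.
#' @export
read_site_metadata <- function(path) {
  df <- read_tsv_checked(path)
  cols <- c(abbrev = "^abbrev", sample_name = "sample.?name",
            site_name = "site.?name", region = "region",
            latitude = "^lat", longitude = "^long", province = "province",
            temperature = "temp", pH = "^ph$")
  idx <- vapply(cols, find_column, integer(1), df = df, path = path)
  out <- data.frame(
    abbrev      = trimws(df[[idx[["abbrev"]]]]),
    sample_name = trimws(df[[idx[["sample_name"]]]]),
    site_name   = trimws(df[[idx[["site_name"]]]]),
    region      = trimws(df[[idx[["region"]]]]),
    latitude    = parse_numeric_field(df[[idx[["latitude"]]]], "latitude", path),
    longitude   = parse_numeric_field(df[[idx[["longitude"]]]], "longitude", path),
    province    = trimws(df[[idx[["province"]]]]),
    temperature = parse_numeric_field(df[[idx[["temperature"]]]], "temperature", path),
    pH          = parse_numeric_field(df[[idx[["pH"]]]], "pH", path),
    stringsAsFactors = FALSE
  )
  bad_t <- which(!is.na(out$temperature) & (out$temperature < 0 | out$temperature > 110))
  if (length(bad_t))
    stop(sprintf("%s: temperature %.1f out of [0, 110] (row %d)",
                 path, out$temperature[bad_t[1L]], bad_t[1L]), call. = FALSE)
  bad_p <- which(!is.na(out$pH) & (out$pH < 0 | out$pH > 14))
  if (length(bad_p))
    stop(sprintf("%s: pH %.2f out of [0, 14] (row %d)",
                 path, out$pH[bad_p[1L]], bad_p[1L]), call. = FALSE)
  out$sample_type <- sample_type_from_id(out$sample_name)
  out
}

#' Write a site metadata table
#'
#' Inverse of [read_site_metadata()]: missing values are written as `NM`
#' and the derived `sample_type` column is dropped.
#'
#' @param metadata data frame as returned by [read_site_metadata()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_metadata <- function(metadata, path) {
  out <- metadata[setdiff(names(metadata), "sample_type")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NM")
  invisible(path)
}

# CAZyme overview tables ------------------------------------------------

TOOL_COLUMNS <- c("HMMER", "eCAMI", "dbCAN_sub", "DIAMOND", "Hotpep")

strip_cazy_call <- function(x) {
  # "GH13_20(31-186)" -> "GH13"; multi-domain calls are "+"-separated
  x <- gsub("\\([^)]*\\)", "", x)
  parts <- strsplit(x, "+", fixed = TRUE)
  lapply(parts, function(p) {
    p <- sub("_.*$", "", trimws(p))
    p[nzchar(p) & p != "-"]
  })
}

#' Read a dbcan-style CAZyme overview table
#'
#' Parses the tab-separated "overview" dialect written by CAZyme annotation
#' pipelines: one row per gene, one column per caller (HMMER, DIAMOND, and
#' optionally eCAMI/dbCAN_sub/Hotpep) holding that caller's family call or
#' `-`. Subfamily suffixes (`GH13_20`) are truncated to the family (`GH13`)
#' and domain coordinates are stripped. No filtering happens here: tool
#' support is recorded for [filter_annotations()] to act on.
#'
#' @param path path to the overview TSV.
#' @return an annotation data frame with one row per (gene, family):
#'   columns `gene_id`, `contig_id` (`NA`, resolved later), `scheme`
#'   (`"CAZY"`), `label`, `tool_support` (`;`-separated caller names) and
#'   `secreted` (`NA`, joined later).
#' @export
read_cazyme_overview <- function(path) {
  df <- read_tsv_checked(path)
  gid <- find_column(df, "gene", path)
  tool_cols <- intersect(TOOL_COLUMNS, names(df))
  if (length(tool_cols) == 0L)
    stop(sprintf("%s: no caller columns (expected some of %s)",
                 path, paste(TOOL_COLUMNS, collapse = ", ")), call. = FALSE)
  # long format: one row per (input row, caller, family call)
  long <- do.call(rbind, lapply(tool_cols, function(tc) {
    fams <- strip_cazy_call(df[[tc]])
    lens <- lengths(fams)
    data.frame(row = rep(seq_len(nrow(df)), lens), tool = tc,
               label = unlist(fams, use.names = FALSE), stringsAsFactors = FALSE)
  }))
  if (is.null(long) || nrow(long) == 0L)
    return(data.frame(gene_id = character(0), contig_id = character(0),
                      scheme = character(0), label = character(0),
                      tool_support = character(0), secreted = logical(0)))
  support <- vapply(split(long$tool, long$row),
                    function(tt) paste(intersect(TOOL_COLUMNS, unique(tt)),
                                       collapse = ";"), character(1))
  long <- long[order(long$row), , drop = FALSE]
  pairs <- long[!duplicated(long[c("row", "label")]), c("row", "label")]
  out <- data.frame(gene_id = df[[gid]][pairs$row], contig_id = NA_character_,
                    scheme = "CAZY", label = pairs$label,
                    tool_support = support[as.character(pairs$row)],
                    secreted = NA, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  check_label_syntax(out)
  out
}

# DRAM-style annotations (MEROPS + EC) ----------------------------------

split_labels <- function(x) {
  # vectorized: returns a list of label vectors, one element per input
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE), function(p) {
    p <- trimws(p)
    p[nzchar(p)]
  })
}

#' Read a DRAM-style annotation table carrying peptidase families and EC numbers
#'
#' Expects a tab-separated table with a gene id column plus a column of
#' MEROPS peptidase family ids and/or a column of EC numbers; multiple
#' labels per gene are `;`-separated. MEROPS subfamily letters (`M23A`) are
#' truncated to the family (`M23`) and `EC ` prefixes are stripped. One
#' output row per (gene, scheme, label); EC class restriction happens in
#' [filter_annotations()], not here.
#'
#' @param path path to the annotation TSV.
#' @return annotation data frame in the layout of [read_cazyme_overview()],
#'   with `scheme` in `"MEROPS"`/`"EC"` and `tool_support = "DRAM"`.
#' @export
read_dram_annotations <- function(path) {
  df <- read_tsv_checked(path)
  gid <- find_column(df, "gene", path)
  mcol <- find_column(df, "peptidase|merops", path, required = FALSE)
  ecol <- find_column(df, "^ec", path, required = FALSE)
  expand_scheme <- function(col, scheme, clean) {
    labs <- lapply(split_labels(df[[col]]), function(p) unique(clean(p)))
    lens <- lengths(labs)
    n <- sum(lens)
    data.frame(gene_id = rep(df[[gid]], lens),
               contig_id = rep(NA_character_, n), scheme = rep(scheme, n),
               label = unlist(labs, use.names = FALSE) %||% character(0),
               tool_support = rep("DRAM", n), secreted = rep(NA, n),
               stringsAsFactors = FALSE)
  }
  parts <- list()
  if (!is.na(mcol))
    parts$merops <- expand_scheme(mcol, "MEROPS",
                                  function(p) sub("^([A-Z][0-9]+).*$", "\\1", p))
  if (!is.na(ecol))
    parts$ec <- expand_scheme(ecol, "EC", function(p) sub("^EC[ :]*", "", p))
  out <- do.call(rbind, unname(parts))
  if (is.null(out))
    out <- data.frame(gene_id = character(0), contig_id = character(0),
                      scheme = character(0), label = character(0),
                      tool_support = character(0), secreted = logical(0))
  # interleave back to input row order so records follow the file
  out <- out[order(match(out$gene_id, df[[gid]])), , drop = FALSE]
  rownames(out) <- NULL
  check_label_syntax(out)
  out
}

check_label_syntax <- function(annots) {
  pat <- c(CAZY = "^(GH|GT|PL|CE|AA|CBM)[0-9]+$",
           MEROPS = "^[A-Z][0-9]+$",
           EC = "^[0-9]+\\.[0-9-]+\\.[0-9-]+\\.[0-9-]+$")
  for (sch in intersect(unique(annots$scheme), names(pat))) {
    lab <- annots$label[annots$scheme == sch]
    bad <- lab[!grepl(pat[[sch]], lab)]
    if (length(bad))
      stop(sprintf("malformed %s label(s): %s", sch,
                   paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(annots)
}

# secretion flags -------------------------------------------------------

#' Read a signal-peptide prediction summary
#'
#' Accepts the summary dialects of signal-peptide predictors: a table with
#' a gene id column and a yes/no or class column. A gene counts as secreted
#' when its value starts with `SP`, `Y`, `yes`, `TRUE` or `1`. Which column
#' defines "secreted" is a user-facing choice via `flag_column`.
#'
#' @param path path to the summary TSV.
#' @param flag_column name of the column holding the prediction; default
#'   picks the first column matching `prediction` or `secreted`.
#' @return character vector (a set: unique) of secreted gene ids.
#' @export
read_secretion_flags <- function(path, flag_column = NULL) {
  df <- read_tsv_checked(path)
  if (nrow(df) == 0L) return(character(0))
  gid <- find_column(df, "gene|^#?\\s*id", path)
  fc <- if (is.null(flag_column)) {
    find_column(df, "prediction|secreted", path)
  } else {
    if (!flag_column %in% names(df))
      stop(sprintf("%s: no column '%s'", path, flag_column), call. = FALSE)
    match(flag_column, names(df))
  }
  pos <- grepl("^(SP|Y|yes|TRUE|1)", trimws(df[[fc]]), ignore.case = FALSE)
  unique(df[[gid]][pos])
}

# gene -> contig map (GFF3) ---------------------------------------------

#' Read a GFF3 gene map
#'
#' Maps feature `ID` attributes of CDS/gene features to their host contig
#' (the GFF3 seqid). Any trailing `##FASTA` section is ignored. Duplicate
#' IDs pointing at different contigs are an error.
#'
#' @param path path to a GFF3 file.
#' @return named character vector: `names` are gene ids, values contig ids.
#' @export
read_gene_map <- function(path) {
  gr <- rtracklayer::import(path)
  keep <- as.character(gr$type) %in% c("CDS", "gene", "mRNA")
  gr <- gr[keep & !is.na(gr$ID)]
  map <- setNames(as.character(GenomicRanges::seqnames(gr)), gr$ID)
  dup <- unique(names(map)[duplicated(names(map))])
  for (d in dup) {
    contigs <- unique(map[names(map) == d])
    if (length(contigs) > 1L)
      stop(sprintf("%s: gene id '%s' maps to multiple contigs (%s)",
                   path, d, paste(contigs, collapse = ", ")), call. = FALSE)
  }
  map[!duplicated(names(map))]
}

#' Write a minimal GFF3 gene map
#'
#' @param genes data frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` (1-based inclusive coordinates).
#' @param path output path.
#' @param fasta optional named character vector of contig sequences to
#'   append as a `##FASTA` section.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(genes, path, fasta = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tgeothermenz\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     genes$contig_id, as.integer(genes$start),
                     as.integer(genes$end), genes$strand, genes$gene_id), con)
  if (!is.null(fasta)) {
    writeLines("##FASTA", con)
    for (nm in names(fasta)) writeLines(c(paste0(">", nm), fasta[[nm]]), con)
  }
  invisible(path)
}

# coverage and assembly stats -------------------------------------------

#' Read a contig coverage table
#'
#' Two dialects are supported. `"summary"` (default) is a TSV with contig
#' id, mean depth and length columns, as produced by coverage summarizers.
#' `"per_base"` is the three-column per-position depth dialect of
#' `samtools depth -a` (contig, position, depth), aggregated here to mean
#' depth per contig with length taken as the number of reported positions.
#'
#' @param path path to the coverage table.
#' @param format `"summary"` or `"per_base"`.
#' @return data frame with columns `contig_id`, `mean_depth`, `length`.
#' @export
read_coverage <- function(path, format = c("summary", "per_base")) {
  format <- match.arg(format)
  if (format == "per_base") {
    df <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(df) < 3L)
      stop(sprintf("%s: per-base depth needs 3 columns", path), call. = FALSE)
    names(df)[1:3] <- c("contig_id", "pos", "depth")
    if (any(df$depth < 0))
      stop(sprintf("%s: negative depth", path), call. = FALSE)
    agg <- aggregate(depth ~ contig_id, df, mean)
    len <- aggregate(pos ~ contig_id, df, length)
    out <- data.frame(contig_id = agg$contig_id, mean_depth = agg$depth,
                      length = len$pos[match(agg$contig_id, len$contig_id)],
                      stringsAsFactors = FALSE)
    return(out)
  }
  df <- read_tsv_checked(path)
  out <- data.frame(
    contig_id = trimws(df[[find_column(df, "contig", path)]]),
    mean_depth = parse_numeric_field(df[[find_column(df, "depth", path)]],
                                     "mean_depth", path),
    length = parse_numeric_field(df[[find_column(df, "length", path)]],
                                 "length", path),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$mean_depth)) || any(out$mean_depth < 0))
    stop(sprintf("%s: mean depth must be >= 0", path), call. = FALSE)
  if (any(is.na(out$length)) || any(out$length < 1))
    stop(sprintf("%s: contig length must be >= 1", path), call. = FALSE)
  out
}

#' @rdname read_coverage
#' @param coverage data frame as returned by `read_coverage()`.
#' @export
write_coverage <- function(coverage, path) {
  write.table(coverage, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an assembly statistics table
#'
#' @param path TSV with columns `sample_id`, `total_length` (bp) and
#'   `n_contigs`.
#' @return data frame with those columns; `total_length` must be positive.
#' @export
read_assembly_stats <- function(path) {
  df <- read_tsv_checked(path)
  out <- data.frame(
    sample_id = trimws(df[[find_column(df, "sample", path)]]),
    total_length = parse_numeric_field(df[[find_column(df, "total_length|total.?size", path)]],
                                       "total_length", path),
    n_contigs = parse_numeric_field(df[[find_column(df, "contig", path)]],
                                    "n_contigs", path),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$total_length)) || any(out$total_length <= 0))
    stop(sprintf("%s: total_length must be > 0", path), call. = FALSE)
  out
}

# packaged reference tables ---------------------------------------------

ref_path <- function(file) {
  system.file("extdata", file, package = "geothermenz", mustWork = TRUE)
}

#' Packaged reference tables for the 63 surveyed geothermal springs
#'
#' `spring_sites()` returns the curated site table (abbreviation, sample
#' name, region, province, coordinates, temperature, pH) for the 63 springs
#' spanning the Central American and Andean convergent margins and Iceland.
#' `reference_substrate_scores()` returns the curated per-assembly sums of
#' cell-degrading (chitin + peptidoglycan) and photosynthate-degrading
#' (xylan + cellulose) enzyme abundance with the reported necromass
#' fraction, as a [substrate_scores][score_table()] table.
#' `reported_class_counts()` returns the per-class counts of secreted
#' enzyme families reported for the survey (MEROPS catalytic types and
#' CAZy classes).
#'
#' @return data frames; see Details.
#' @export
spring_sites <- function() {
  read_site_metadata(ref_path("springs_sites.tsv"))
}

#' @rdname spring_sites
#' @export
reference_substrate_scores <- function() {
  df <- read_tsv_checked(ref_path("cell_photosynthate_sums.tsv"))
  out <- data.frame(
    sample_id = df$site,
    cell_abundance = as.numeric(df$cell),
    photo_abundance = as.numeric(df$plant),
    province = df$province,
    sample_type = tolower(df$type),
    temperature = parse_numeric_field(df$temperature, "temperature", "reference"),
    pH = parse_numeric_field(df$pH, "pH", "reference"),
    reported_fraction = as.numeric(df$pct_cell),
    stringsAsFactors = FALSE
  )
  out$necromass_fraction <- necromass_fraction(out$cell_abundance, out$photo_abundance)
  class(out) <- c("substrate_scores", "data.frame")
  attr(out, "totals") <- c(cell = sum(out$cell_abundance),
                           photosynthate = sum(out$photo_abundance))
  out
}

#' @rdname spring_sites
#' @export
reported_class_counts <- function() {
  df <- read_tsv_checked(ref_path("annotation_class_counts.tsv"))
  df$n_families <- as.integer(df$n_families)
  df
}
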