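# Substrate-group scoring: map enzyme families to the six substrate groups
# (chitin, peptidoglycan, starch/glycogen, trehalose, xylan, cellulose),
# sum the cell supergroup (chitin + peptidoglycan, i.e. microbial
# necromass) against the photosynthate supergroup (xylan + cellulose), and
# report the necromass fraction cell / (cell + photosynthate) per sample.

SUPERGROUPS <- list(cell = c("chitin", "peptidoglycan"),
                    photosynthate = c("xylan", "cellulose"))

#' Family-to-substrate-group map
#'
#' Loads a (group, scheme, family) table mapping enzyme families to the
#' substrate groups `chitin`, `peptidoglycan`, `starch_glycogen`,
#' `trehalose`, `xylan` and `cellulose`. The packaged default is the
#' curated map used for the 63-spring survey; a family may belong to
#' several groups (GH5 sits in chitin, xylan and cellulose). Supergroups
#' are fixed: `cell` = chitin + peptidoglycan, `photosynthate` = xylan +
#' cellulose.
#'
#' @param path optional path to a user map in the same three-column TSV
#'   layout; default uses the packaged map.
#' @return an object of class `substrate_group_map`: list with `table`
#'   (the raw data frame), `groups` (named list of family vectors) and
#'   `supergroups`.
#' @export
substrate_group_map <- function(path = NULL) {
  path <- path %||% ref_path("substrate_group_families.tsv")
  df <- read_tsv_checked(path)
  need <- c("group", "scheme", "family")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: substrate map needs columns %s",
                 path, paste(need, collapse = ", ")), call. = FALSE)
  structure(list(table = df,
                 groups = lapply(split(df$family, df$group), unique),
                 supergroups = SUPERGROUPS),
            class = "substrate_group_map")
}

#' @export
print.substrate_group_map <- function(x, ...) {
  cat("substrate_group_map:\n")
  for (g in names(x$groups))
    cat(sprintf("  %-16s %s\n", g, paste(x$groups[[g]], collapse = " ")))
  invisible(x)
}

#' Families belonging to a substrate supergroup
#'
#' The union of the families of a supergroup's member groups, restricted
#' to the requested schemes. `dedup = "exclusive"` additionally removes
#' families that the map also lists under the other supergroup.
#'
#' @param map a [substrate_group_map()].
#' @param supergroup `"cell"` or `"photosynthate"`.
#' @param schemes annotation schemes to include.
#' @param dedup see [group_abundance()].
#' @return character vector of family labels.
#' @export
supergroup_families <- function(map, supergroup, schemes,
                                dedup = c("within_supergroup", "exclusive")) {
  dedup <- match.arg(dedup)
  if (!supergroup %in% names(map$supergroups))
    stop(sprintf("unknown supergroup '%s' (have: %s)", supergroup,
                 paste(names(map$supergroups), collapse = ", ")), call. = FALSE)
  tab <- map$table[map$table$scheme %in% schemes, , drop = FALSE]
  fams_of <- function(sg) unique(tab$family[tab$group %in% map$supergroups[[sg]]])
  fams <- fams_of(supergroup)
  if (dedup == "exclusive") {
    other <- setdiff(names(map$supergroups), supergroup)
    fams <- setdiff(fams, unique(unlist(lapply(other, fams_of))))
  }
  fams
}

#' Per-sample abundance of a substrate supergroup
#'
#' Sums, for every sample, the abundances of the distinct families in the
#' supergroup's union of member groups. A family listed in two member
#' groups (GH5 in both xylan and cellulose) is counted once per
#' supergroup. By default only CAZy families are scored; pass
#' `schemes = c("CAZY", "MEROPS")` to pool peptidase families in as well.
#'
#' @param matrices a single `abundance_matrix` or a named list of them
#'   (names = schemes); all must share the sample set.
#' @param map a [substrate_group_map()].
#' @param supergroup `"cell"` or `"photosynthate"`.
#' @param schemes annotation schemes to pool (default `"CAZY"`).
#' @param dedup `"within_supergroup"` counts a family once per supergroup
#'   even when it is listed under both supergroups; `"exclusive"` drops
#'   families shared between the two supergroups entirely.
#' @return named numeric vector of per-sample abundances.
#' @export
group_abundance <- function(matrices, map, supergroup, schemes = "CAZY",
                            dedup = c("within_supergroup", "exclusive")) {
  dedup <- match.arg(dedup)
  if (is.matrix(matrices)) {
    matrices <- setNames(list(matrices),
                         attr(matrices, "scheme") %||% schemes[1L])
  }
  samples <- colnames(matrices[[1L]])
  for (m in matrices)
    if (!identical(colnames(m), samples))
      stop("matrices must share an identical sample set", call. = FALSE)
  fams <- supergroup_families(map, supergroup, schemes, dedup)
  out <- setNames(numeric(length(samples)), samples)
  for (sch in intersect(schemes, names(matrices))) {
    m <- matrices[[sch]]
    rows <- intersect(fams, rownames(m))
    if (length(rows))
      out <- out + colSums(m[rows, , drop = FALSE])
  }
  out
}

#' Necromass fraction: cell / (cell + photosynthate)
#'
#' The share of grouped enzyme abundance targeting microbial cell material
#' (chitin + peptidoglycan) rather than photosynthate (xylan + cellulose).
#' Undefined (NA) when both sums are zero. Vectorized.
#'
#' @param cell,photo non-negative abundances.
#' @return numeric vector in `[0, 1]`, NA where `cell + photo == 0`.
#' @examples
#' necromass_fraction(2303.35, 7311.38) # 0.2396
#' @export
necromass_fraction <- function(cell, photo) {
  if (any(cell < 0, na.rm = TRUE) || any(photo < 0, na.rm = TRUE))
    stop("abundances must be >= 0", call. = FALSE)
  out <- cell / (cell + photo)
  out[(cell + photo) == 0] <- NA_real_
  out
}

#' Score samples by cell vs photosynthate enzyme abundance
#'
#' Builds the per-sample substrate score table: cell and photosynthate
#' supergroup sums, the necromass fraction, and site metadata, sorted by
#' ascending fraction. Column totals are attached as an attribute.
#'
#' @inheritParams group_abundance
#' @param metadata data frame with columns `sample_id`, `province`,
#'   `sample_type`, `temperature`, `pH` covering every sample (see
#'   [metadata_by_sample()]).
#' @return a `substrate_scores` data frame with columns `sample_id`,
#'   `cell_abundance`, `photo_abundance`, `province`, `sample_type`,
#'   `temperature`, `pH`, `necromass_fraction`, plus attribute `totals`.
#' @export
score_table <- function(matrices, map, metadata, schemes = "CAZY",
                        dedup = c("within_supergroup", "exclusive")) {
  dedup <- match.arg(dedup)
  cell <- group_abundance(matrices, map, "cell", schemes, dedup)
  photo <- group_abundance(matrices, map, "photosynthate", schemes, dedup)
  samples <- names(cell)
  midx <- match(samples, metadata$sample_id)
  if (anyNA(midx))
    stop(sprintf("sample(s) missing from metadata: %s",
                 paste(samples[is.na(midx)], collapse = ", ")), call. = FALSE)
  out <- data.frame(
    sample_id = samples,
    cell_abundance = unname(cell),
    photo_abundance = unname(photo),
    province = metadata$province[midx],
    sample_type = metadata$sample_type[midx],
    temperature = metadata$temperature[midx],
    pH = metadata$pH[midx],
    necromass_fraction = unname(necromass_fraction(cell, photo)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$necromass_fraction, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("substrate_scores", "data.frame")
  attr(out, "totals") <- c(cell = sum(out$cell_abundance),
                           photosynthate = sum(out$photo_abundance))
  out
}

#' @export
print.substrate_scores <- function(x, ...) {
  cat(sprintf("substrate_scores: %d samples\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat("...\n")
  tot <- attr(x, "totals")
  if (!is.null(tot))
    cat(sprintf("totals: cell %.2f, photosynthate %.2f\n",
                tot[["cell"]], tot[["photosynthate"]]))
  invisible(x)
}

#' @export
summary.substrate_scores <- function(object, frac_threshold = 0.5,
                                     photo_share_threshold = 0.3, ...) {
  fr <- object$necromass_fraction
  res <- list(
    n_samples = nrow(object),
    totals = attr(object, "totals"),
    n_below_threshold = sum(fr < frac_threshold, na.rm = TRUE),
    frac_threshold = frac_threshold,
    n_high_photo_share = sum((1 - fr) > photo_share_threshold, na.rm = TRUE),
    n_high_photo_share_sediment = sum((1 - fr) > photo_share_threshold &
                                        object$sample_type == "sediment",
                                      na.rm = TRUE),
    photo_share_threshold = photo_share_threshold,
    n_undefined = sum(is.na(fr))
  )
  class(res) <- "summary.substrate_scores"
  res
}

#' @export
print.summary.substrate_scores <- function(x, ...) {
  cat(sprintf("%d samples; totals cell %.2f / photosynthate %.2f\n",
              x$n_samples, x$totals[["cell"]], x$totals[["photosynthate"]]))
  cat(sprintf("%d samples with necromass fraction < %.2f\n",
              x$n_below_threshold, x$frac_threshold))
  cat(sprintf("%d samples with photosynthate share > %.2f (%d sediments)\n",
              x$n_high_photo_share, x$photo_share_threshold,
              x$n_high_photo_share_sediment))
  if (x$n_undefined > 0)
    cat(sprintf("%d samples with undefined fraction (no grouped abundance)\n",
                x$n_undefined))
  invisible(x)
}

#' Stacked cell/photosynthate sums by province and sample type
#'
#' Aggregates a score table into per-(province, sample type) sums of cell
#' and photosynthate abundance - the stacked-bar view of the fluid versus
#' sediment contrast - plus overall fluid and sediment sums.
#'
#' @param scores a `substrate_scores` table.
#' @return list with `by_group` (data frame province x sample_type with
#'   cell/photo sums) and `overall` (2 x 2 matrix: sums by sample type).
#' @export
fluid_sediment_summary <- function(scores) {
  df <- as.data.frame(scores)
  by_group <- aggregate(cbind(cell_abundance, photo_abundance) ~
                          province + sample_type, data = df, FUN = sum)
  by_group <- by_group[order(by_group$province, by_group$sample_type), ,
                       drop = FALSE]
  rownames(by_group) <- NULL
  types <- sort(unique(df$sample_type))
  overall <- vapply(types, function(tt) {
    i <- df$sample_type == tt
    c(cell = sum(df$cell_abundance[i]), photosynthate = sum(df$photo_abundance[i]))
  }, numeric(2))
  list(by_group = by_group, overall = overall)
}

#' Write a substrate score table as TSV
#'
#' @param scores a `substrate_scores` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Round a necromass fraction for reporting
#'
#' Two decimal places with round-half-even, matching how the survey's
#' score tables are printed.
#'
#' @param fraction numeric vector.
#' @return rounded vector.
#' @export
report_fraction <- function(fraction) round(fraction, 2L)
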