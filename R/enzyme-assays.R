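# Fluorometric extracellular enzyme assays: sediment slurries incubated
# with methylumbelliferyl-/methylcoumarin-linked substrate proxies, read
# at three timepoints, converted to potential hydrolysis rates in
# umol per g wet sediment per hour.

ASSAY_SUBSTRATES <- c("AG", "BG", "CB", "NAG", "LEU", "PHOS", "SULF", "XYL")

#' Slurry bookkeeping for the plate assay
#'
#' The default protocol: 2.75 g wet sediment homogenized into 91 mL of
#' 0.5 M Tris-HCl buffer (pH matched to the site), 0.8 mL slurry aliquots
#' per deep well plus 0.2 mL of 200 uM substrate. Sediment volume is
#' neglected in the slurry concentration (no slurry density is assumed).
#'
#' @param sediment_mass g wet sediment in the slurry.
#' @param buffer_volume mL of buffer.
#' @param aliquot_volume mL of slurry pipetted per well.
#' @param substrate_volume mL of substrate solution added per well.
#' @param substrate_stock substrate concentration, uM.
#' @return object of class `slurry_spec`.
#' @export
slurry_spec <- function(sediment_mass = 2.75, buffer_volume = 91,
                        aliquot_volume = 0.8, substrate_volume = 0.2,
                        substrate_stock = 200) {
  check_pos(sediment_mass, "sediment_mass")
  check_pos(buffer_volume, "buffer_volume")
  check_pos(aliquot_volume, "aliquot_volume")
  check_pos(substrate_volume, "substrate_volume")
  check_pos(substrate_stock, "substrate_stock")
  structure(list(sediment_mass = sediment_mass, buffer_volume = buffer_volume,
                 aliquot_volume = aliquot_volume,
                 substrate_volume = substrate_volume,
                 substrate_stock = substrate_stock),
            class = "slurry_spec")
}

well_volume_l <- function(spec) {
  (spec$aliquot_volume + spec$substrate_volume) / 1000
}

#' Wet sediment mass per assay well
#'
#' The slurry aliquot carries `sediment_mass * aliquot_volume /
#' buffer_volume` grams of wet sediment (sediment volume ignored). With
#' the default protocol this is 2.75 x 0.8 / 91 = 0.0242 g.
#'
#' @param spec a [slurry_spec()].
#' @return g wet sediment per well.
#' @export
sediment_mass_per_well <- function(spec = slurry_spec()) {
  spec$sediment_mass * spec$aliquot_volume / spec$buffer_volume
}

#' Fluorophore standard curve
#'
#' `calibration()` builds one directly; `fit_calibration()` fits slope and
#' intercept by ordinary least squares from a standards table.
#'
#' @param slope fluorescence units per uM of free fluorophore (> 0).
#' @param intercept fluorescence units at zero fluorophore.
#' @return object of class `fluor_calibration`.
#' @export
calibration <- function(slope, intercept = 0) {
  check_pos(slope, "slope")
  structure(list(slope = slope, intercept = intercept),
            class = "fluor_calibration")
}

#' @rdname calibration
#' @param standards data frame with columns `concentration` (uM) and
#'   `fluorescence`.
#' @export
fit_calibration <- function(standards) {
  fit <- lm(fluorescence ~ concentration, data = standards)
  calibration(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]))
}

#' @rdname calibration
#' @param path TSV with the standards table.
#' @export
read_calibration <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  fit_calibration(df)
}

#' A fluorometric assay plate time series
#'
#' One sample x substrate combination: fluorescence readings for duplicate
#' wells at each timepoint (default 0, 1.5 and 3 h).
#'
#' @param sample_id sample identifier (sediment samples only are assayed).
#' @param substrate one of `r paste(ASSAY_SUBSTRATES, collapse = ", ")`.
#' @param timepoints hours, strictly increasing, at least two.
#' @param fluorescence numeric matrix, replicates x timepoints, >= 0.
#' @param temperature incubation temperature, degC.
#' @param pH buffer pH.
#' @return object of class `assay_plate`.
#' @export
assay_plate <- function(sample_id, substrate, timepoints, fluorescence,
                        temperature = NA_real_, pH = NA_real_) {
  substrate <- match.arg(substrate, ASSAY_SUBSTRATES)
  if (length(timepoints) < 2L)
    stop("an assay needs at least 2 timepoints", call. = FALSE)
  if (any(diff(timepoints) <= 0))
    stop("timepoints must be strictly increasing", call. = FALSE)
  fluorescence <- as.matrix(fluorescence)
  if (ncol(fluorescence) != length(timepoints))
    stop("fluorescence needs one column per timepoint", call. = FALSE)
  if (any(fluorescence < 0))
    stop("fluorescence must be >= 0", call. = FALSE)
  structure(list(sample_id = sample_id, substrate = substrate,
                 timepoints = as.numeric(timepoints),
                 fluorescence = fluorescence, temperature = temperature,
                 pH = pH),
            class = "assay_plate")
}

#' @export
print.assay_plate <- function(x, ...) {
  cat(sprintf("assay_plate: %s / %s, %d replicates at %s h\n", x$sample_id,
              x$substrate, nrow(x$fluorescence),
              paste(x$timepoints, collapse = ", ")))
  invisible(x)
}

#' Potential hydrolysis rate from a plate time series
#'
#' Per replicate well: the ordinary-least-squares slope of fluorescence
#' against time (FU/h) is divided by the calibration slope (FU/uM) to give
#' a fluorophore release rate in uM/h, converted to umol/h via the well
#' volume, and divided by the wet sediment mass per well - yielding
#' umol g_wet^-1 h^-1. Replicates are averaged; negative rates are
#' reported as-is, never clipped. Optional blanks (substrate-only and
#' slurry-only plates) are subtracted from the slope first.
#'
#' @param plate an [assay_plate()].
#' @param cal a [calibration()] (the additive intercept cancels in the
#'   slope).
#' @param spec a [slurry_spec()].
#' @param substrate_blank,slurry_blank optional `assay_plate`s whose mean
#'   fluorescence slopes are subtracted.
#' @return object of class `hydrolysis_rate`: list with `rate` (mean over
#'   replicates, umol/g wet/h), `per_replicate`, `sample_id`, `substrate`.
#' @export
hydrolysis_rate <- function(plate, cal, spec = slurry_spec(),
                            substrate_blank = NULL, slurry_blank = NULL) {
  slope_fu <- function(p) {
    apply(p$fluorescence, 1L, function(y) {
      unname(coef(lm(y ~ p$timepoints))[2L])
    })
  }
  slopes <- slope_fu(plate)
  for (blank in list(substrate_blank, slurry_blank))
    if (!is.null(blank)) slopes <- slopes - mean(slope_fu(blank))
  conc_rate <- slopes / cal$slope                 # uM / h
  umol_per_h <- conc_rate * well_volume_l(spec)   # uM * L = umol
  per_rep <- umol_per_h / sediment_mass_per_well(spec)
  structure(list(rate = mean(per_rep), per_replicate = per_rep,
                 sample_id = plate$sample_id, substrate = plate$substrate),
            class = "hydrolysis_rate")
}

#' @export
print.hydrolysis_rate <- function(x, ...) {
  cat(sprintf("%s / %s: %.4g umol g_wet^-1 h^-1 (replicates: %s)\n",
              x$sample_id, x$substrate, x$rate,
              paste(signif(x$per_replicate, 4), collapse = ", ")))
  invisible(x)
}

#' Tabulate hydrolysis rates for a set of plates
#'
#' @param plates list of [assay_plate()]s.
#' @param cal a [calibration()].
#' @param spec a [slurry_spec()].
#' @return data frame with columns `sample_id`, `substrate`, `rate`.
#' @export
rate_table <- function(plates, cal, spec = slurry_spec()) {
  rows <- lapply(plates, function(p) {
    r <- hydrolysis_rate(p, cal, spec)
    data.frame(sample_id = r$sample_id, substrate = r$substrate,
               rate = r$rate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Kruskal-Wallis comparison of hydrolysis rates across provinces
#'
#' One test per substrate. Assays are run on sediment samples only; the
#' comparison refuses rates attributed to fluid samples.
#'
#' @param rates data frame with columns `sample_id`, `substrate`, `rate`
#'   (see [rate_table()]).
#' @param metadata data frame with `sample_id`, `province`, `sample_type`.
#' @return named list of [kruskal_wallis()] results, one per substrate.
#' @export
province_comparison <- function(rates, metadata) {
  idx <- match(rates$sample_id, metadata$sample_id)
  if (anyNA(idx))
    stop(sprintf("sample(s) missing from metadata: %s",
                 paste(unique(rates$sample_id[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  type <- metadata$sample_type[idx]
  if (any(type == "fluid", na.rm = TRUE))
    stop("hydrolysis assays are defined for sediment samples only; ",
         "fluid sample(s) present: ",
         paste(unique(rates$sample_id[type == "fluid"]), collapse = ", "),
         call. = FALSE)
  province <- metadata$province[idx]
  out <- lapply(split(seq_len(nrow(rates)), rates$substrate), function(i) {
    kruskal_wallis(rates$rate[i], province[i], label = rates$substrate[i][1L])
  })
  out
}

#' Read / write assay plates in long-format TSV
#'
#' Long format: columns `sample_id`, `substrate`, `replicate`, `hour`,
#' `fluorescence`; one [assay_plate()] is assembled per
#' (sample, substrate).
#'
#' @param path TSV path.
#' @return list of `assay_plate` objects (read); `path` invisibly (write).
#' @export
read_assay_plates <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "substrate", "replicate", "hour", "fluorescence")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: assay table needs columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  keys <- unique(df[c("sample_id", "substrate")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$sample_id == keys$sample_id[i] &
                df$substrate == keys$substrate[i], , drop = FALSE]
    hours <- sort(unique(sub$hour))
    reps <- sort(unique(sub$replicate))
    fl <- matrix(NA_real_, length(reps), length(hours))
    fl[cbind(match(sub$replicate, reps), match(sub$hour, hours))] <-
      sub$fluorescence
    assay_plate(keys$sample_id[i], keys$substrate[i], hours, fl)
  })
}

#' @rdname read_assay_plates
#' @param plates list of `assay_plate` objects.
#' @export
write_assay_plates <- function(plates, path) {
  rows <- lapply(plates, function(p) {
    data.frame(sample_id = p$sample_id, substrate = p$substrate,
               replicate = rep(seq_len(nrow(p$fluorescence)),
                               times = length(p$timepoints)),
               hour = rep(p$timepoints, each = nrow(p$fluorescence)),
               fluorescence = as.vector(p$fluorescence),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
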