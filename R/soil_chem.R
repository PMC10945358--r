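#' Construct a CO2 incubation record
#'
#' Bundles the physical parameters of one closed-flask CO2 incubation used
#' to compute the soil carbon mineralization rate (CMR). Units follow the
#' bookkeeping documented in [compute_cmr()].
#'
#' @param c0,c1 Headspace CO2 concentration at the start (T0) and end (T1)
#'   of the incubation, in volume ppm.
#' @param void_volume_V Headspace (void) volume of the flask, litres.
#' @param soil_mass_m Fresh soil mass, kilograms.
#' @param duration_dt Incubation duration, days.
#' @param temperature_T Incubation temperature, degrees Celsius.
#' @param soc Soil organic carbon content, g C per kg soil.
#' @param molar_mass_M Molar mass applied to the CO2 increment, g per mol.
#'   Fixed at 12 (the carbon in CO2) because CMR is expressed in mg C;
#'   configurable for audit only.
#' @param molar_volume Molar volume of an ideal gas at standard conditions,
#'   L per mol (22.4).
#' @return An object of class `incubation_record`.
#' @export
incubation_record <- function(c0, c1, void_volume_V, soil_mass_m,
                              duration_dt, temperature_T, soc,
                              molar_mass_M = 12, molar_volume = 22.4) {
  num1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
    v
  }
  rec <- list(
    c0 = num1(c0, "c0"), c1 = num1(c1, "c1"),
    void_volume_V = num1(void_volume_V, "void_volume_V"),
    soil_mass_m = num1(soil_mass_m, "soil_mass_m"),
    duration_dt = num1(duration_dt, "duration_dt"),
    temperature_T = num1(temperature_T, "temperature_T"),
    soc = num1(soc, "soc"),
    molar_mass_M = num1(molar_mass_M, "molar_mass_M"),
    molar_volume = num1(molar_volume, "molar_volume")
  )
  if (rec$c0 < 0 || rec$c1 < 0) {
    stop("CO2 concentrations `c0` and `c1` must be non-negative",
         call. = FALSE)
  }
  if (rec$void_volume_V <= 0) stop("`void_volume_V` must be > 0", call. = FALSE)
  structure(rec, class = "incubation_record")
}

#' Soil carbon mineralization rate from a closed incubation
#'
#' Computes CMR = dc * V * M / (m * dt * 22.4) * alpha / SOC with
#' alpha = 273 / (273 + T), where dc = c1 - c0 is the rise in headspace CO2
#' over the incubation.
#'
#' Unit bookkeeping (all conversions live here): dc in volume ppm is
#' micromol CO2 per mol of headspace gas, so dc * V / 22.4 * alpha is
#' micromol CO2 produced; multiplying by M = 12 g/mol gives microgram C.
#' Dividing by soil mass (kg) and duration (days) gives microgram C per kg
#' soil per day, and dividing by SOC in g C per kg soil yields
#' mg C per kg SOC per day — the units in which CMR is reported.
#'
#' @param rec An [incubation_record()].
#' @return CMR in mg C per kg SOC per day.
#' @examples
#' rec <- incubation_record(c0 = 400, c1 = 900, void_volume_V = 0.25,
#'                          soil_mass_m = 0.03, duration_dt = 10 / 24,
#'                          temperature_T = 20, soc = 250)
#' compute_cmr(rec)
#' @export
compute_cmr <- function(rec) {
  stopifnot(inherits(rec, "incubation_record"))
  for (fld in c("soil_mass_m", "duration_dt", "soc")) {
    if (rec[[fld]] <= 0) {
      stop("`", fld, "` must be > 0 to compute CMR (division guard)",
           call. = FALSE)
    }
  }
  dc <- rec$c1 - rec$c0
  alpha <- 273 / (273 + rec$temperature_T)
  dc * rec$void_volume_V * rec$molar_mass_M /
    (rec$soil_mass_m * rec$duration_dt * rec$molar_volume) * alpha / rec$soc
}

#' Batch CMR computation over an incubation table
#'
#' Applies [compute_cmr()] row-wise to a table of incubation records and
#' returns a trait-table fragment ready to append to a soil trait table.
#'
#' @param records A data.frame with columns `sample_id`, `c0`, `c1`,
#'   `void_volume_V`, `soil_mass_m`, `duration_dt`, `temperature_T`, `soc`.
#' @return A data.frame with columns `sample_id` and `CMR`.
#' @export
compute_cmr_table <- function(records) {
  needed <- c("sample_id", "c0", "c1", "void_volume_V", "soil_mass_m",
              "duration_dt", "temperature_T", "soc")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("incubation table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cmr <- vapply(seq_len(nrow(records)), function(i) {
    rec <- incubation_record(
      c0 = records$c0[i], c1 = records$c1[i],
      void_volume_V = records$void_volume_V[i],
      soil_mass_m = records$soil_mass_m[i],
      duration_dt = records$duration_dt[i],
      temperature_T = records$temperature_T[i],
      soc = records$soc[i]
    )
    compute_cmr(rec)
  }, numeric(1))
  data.frame(sample_id = records$sample_id, CMR = cmr,
             stringsAsFactors = FALSE)
}

#' FTIR recalcitrance index (1630/1030 peak-area ratio)
#'
#' Ratio of the corrected peak area near 1630 cm-1 (lignin, aromatics and
#' aromatic/aliphatic carboxylates — recalcitrant C) to the area near
#' 1030 cm-1 (polysaccharides — labile C). Higher values indicate a more
#' recalcitrant soil organic matter pool.
#'
#' @param peak_area_1630,peak_area_1030 Corrected peak areas (same units).
#' @return The unitless area ratio.
#' @export
ftir_recalcitrance_ratio <- function(peak_area_1630, peak_area_1030) {
  if (peak_area_1630 < 0 || peak_area_1030 < 0) {
    stop("peak areas must be non-negative", call. = FALSE)
  }
  if (peak_area_1030 == 0) {
    stop("`peak_area_1030` is zero: the 1630/1030 ratio is undefined",
         call. = FALSE)
  }
  peak_area_1630 / peak_area_1030
}

#' Carbohydrate content from the FTIR calibration line
#'
#' Estimates carbohydrate content (%) from the area-normalized FTIR peak
#' height near 1030 cm-1 (`carb`) via the cellulose + hemicellulose
#' calibration line 49204 * carb - 1.7606. Peak heights below the
#' calibration range yield negative percentages; these are returned
#' unclamped with a `below_range` flag (and a warning) so the out-of-range
#' condition stays auditable.
#'
#' @param carb_peak_height Area-normalized peak height near 1030 cm-1
#'   (unitless, >= 0).
#' @return A list with `percent` (the calibration value) and `below_range`
#'   (TRUE when the value is negative).
#' @export
carbohydrate_content <- function(carb_peak_height) {
  if (!is.numeric(carb_peak_height) || any(carb_peak_height < 0)) {
    stop("`carb_peak_height` must be non-negative", call. = FALSE)
  }
  pct <- 49204 * carb_peak_height - 1.7606
  below <- pct < 0
  if (any(below)) {
    warning("carbohydrate calibration returned ", sum(below),
            " value(s) below the calibration range (negative %)",
            call. = FALSE)
  }
  list(percent = pct, below_range = below)
}

#' Carbohydrate fraction of dissolved organic carbon
#'
#' Converts a carbohydrate percentage into the carbohydrate share of DOC:
#' `total_doc * carb_percent / 100`.
#'
#' @param total_doc Total dissolved organic carbon, mg C per litre.
#' @param carb_percent Carbohydrate content, percent of DOC.
#' @return Carbohydrate-C concentration, mg C per litre.
#' @export
doc_carbohydrates <- function(total_doc, carb_percent) {
  if (any(total_doc < 0)) stop("`total_doc` must be >= 0", call. = FALSE)
  if (any(carb_percent < 0)) stop("`carb_percent` must be >= 0", call. = FALSE)
  total_doc * carb_percent / 100
}
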