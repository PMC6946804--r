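# FTICR-MS mass-difference counting: peak pairs separated by one oxygen or
# one carbon, and the O:C transformation ratio by depth.

#' Standard mass transformations
#'
#' Exact monoisotopic mass deltas for the two transformations compared in the
#' O:C ratio: gain of one oxygen (15.994915 Da, the mark of a monooxygenase)
#' and gain of one carbon (12.000000 Da, the most common spacing in DOM
#' spectra).
#'
#' @return `data.frame` with columns `name`, `delta_mass`.
#' @export
mass_transformations <- function() {
  data.frame(name = c("O", "C"), delta_mass = c(MASS_O, MASS_C),
             stringsAsFactors = FALSE)
}

#' Deduplicate and sort an m/z vector
#'
#' Peaks are treated as neutral monoisotopic masses: sorted ascending, values
#' within 1e-6 Da collapsed to one peak.
#'
#' @param mz Numeric vector of masses (Da), strictly positive.
#' @return Sorted, deduplicated numeric vector.
#' @export
dedupe_mz <- function(mz) {
  mz <- as.numeric(mz)
  if (anyNA(mz) || any(mz <= 0)) stop_input("m/z values must be positive and non-missing")
  mz <- sort(mz)
  if (length(mz) < 2) return(mz)
  mz[c(TRUE, diff(mz) > 1e-6)]
}

#' Count peak pairs separated by a fixed mass difference
#'
#' Counts unordered peak pairs (a, b), b > a, with
#' |(b - a) - delta| <= tol, where the tolerance is `tol_ppm` parts per
#' million of the heavier peak (FTICR instruments are specified in ppm), or a
#' fixed `tol_da` in daltons when given. Implemented as a vectorized sweep
#' over the sorted list (a sorted-window two-pointer equivalent), O(n log n)
#' rather than the naive all-pairs O(n^2).
#'
#' @param mz Peak masses; deduplicated and sorted internally.
#' @param delta_mass Transformation mass (Da, > 0).
#' @param tol_ppm Relative tolerance in ppm of the heavier peak (default 1).
#' @param tol_da Absolute tolerance in Da; overrides `tol_ppm` when given.
#' @return Integer pair count.
#' @export
count_mass_differences <- function(mz, delta_mass, tol_ppm = 1, tol_da = NULL) {
  delta_mass <- check_number(delta_mass, "delta_mass", min = 1e-12)
  mz <- dedupe_mz(mz)
  n <- length(mz)
  if (n < 2) return(0L)
  tol <- if (!is.null(tol_da)) rep(check_number(tol_da, "tol_da", min = 0), n)
         else check_number(tol_ppm, "tol_ppm", min = 1e-12) * 1e-6 * mz
  # for each heavier peak b, count lighter peaks in [b - delta - tol_b, b - delta + tol_b]
  hi <- findInterval(mz - delta_mass + tol, mz)                    # mz <= upper bound
  lo <- findInterval(mz - delta_mass - tol, mz, left.open = TRUE)  # mz <  lower bound
  as.integer(sum(hi - lo))
}

#' Per-sample transformation counts and O:C ratio
#'
#' Counts pairs for every requested transformation and reports the ratio of
#' one-oxygen to one-carbon pair counts. Intensities, if the caller has them,
#' play no role: observations are counted, not weighted.
#'
#' @param mz Peak masses for one sample.
#' @param transformations `data.frame` (`name`, `delta_mass`), default
#'   [mass_transformations()].
#' @param tol_ppm,tol_da Matching tolerance, as in [count_mass_differences()].
#' @param sample_id Optional sample label.
#' @return One-row `data.frame`: `sample_id`, one count column per
#'   transformation, and `o_to_c_ratio` (0 when O = 0 and C > 0; `NA` with a
#'   warning when C = 0).
#' @export
transformation_profile <- function(mz, transformations = mass_transformations(),
                                   tol_ppm = 1, tol_da = NULL,
                                   sample_id = NA_character_) {
  transformations <- as.data.frame(transformations)
  check_columns(transformations, c("name", "delta_mass"), "transformations")
  if (!nrow(transformations)) stop_input("'transformations' must be non-empty")
  counts <- vapply(transformations$delta_mass, function(d)
    count_mass_differences(mz, d, tol_ppm = tol_ppm, tol_da = tol_da), 1L)
  names(counts) <- paste0("n_", transformations$name)
  out <- as.data.frame(as.list(counts))
  out <- cbind(data.frame(sample_id = sample_id, stringsAsFactors = FALSE), out)
  o <- if ("n_O" %in% names(counts)) counts[["n_O"]] else NA_integer_
  cc <- if ("n_C" %in% names(counts)) counts[["n_C"]] else NA_integer_
  if (!is.na(cc) && cc == 0) {
    warning("one-carbon pair count is 0; O:C ratio undefined for sample ",
            sample_id)
    out$o_to_c_ratio <- NA_real_
  } else {
    out$o_to_c_ratio <- o / cc
  }
  out
}

#' Transformation counts ordered by station and depth
#'
#' Joins per-sample transformation counts to sample metadata and returns a
#' long table sorted by station label then depth ascending — the layout of a
#' depth-profile figure. Output is independent of input row order.
#'
#' @param counts `data.frame` of rows from [transformation_profile()].
#' @param samples Sample table with `sample_id`, `station`, `depth_m`.
#' @return Long `data.frame`: `station`, `depth_m`, `sample_id`,
#'   `transformation`, `count`, `o_to_c_ratio`.
#' @export
msdiff_depth_profile <- function(counts, samples) {
  check_columns(samples, c("sample_id", "station", "depth_m"), "samples")
  unknown <- setdiff(counts$sample_id, samples$sample_id)
  if (length(unknown))
    stop_input("unknown sample id(s): ", paste(unknown, collapse = ", "))
  cnt_cols <- grep("^n_", names(counts), value = TRUE)
  i <- match(counts$sample_id, samples$sample_id)
  long <- do.call(rbind, lapply(cnt_cols, function(cc)
    data.frame(station = samples$station[i], depth_m = samples$depth_m[i],
               sample_id = counts$sample_id,
               transformation = sub("^n_", "", cc), count = counts[[cc]],
               o_to_c_ratio = counts$o_to_c_ratio,
               stringsAsFactors = FALSE)))
  long <- long[order(long$station, long$depth_m, long$transformation), ]
  rownames(long) <- NULL
  long
}

#' Read a peak-list CSV
#'
#' Expects a column `mz` (optional extra columns such as intensity are
#' ignored for counting).
#'
#' @param file Path to the CSV.
#' @return Sorted, deduplicated numeric m/z vector.
#' @export
read_peaklist <- function(file) {
  df <- read.table(file, sep = ",", header = TRUE)
  check_columns(df, "mz", basename(file))
  dedupe_mz(df$mz)
}
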