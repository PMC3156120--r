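#' Floor intensities at the reliable-detection limit
#'
#' Microarray intensities below the detection limit are indistinguishable from
#' background; every value below `floor` is raised to `floor` so that
#' downstream log-ratios of undetected miRs are exactly zero.
#'
#' @param x Expression tibble (`mir_id` + sample columns).
#' @param floor Detection limit in intensity units (default 200).
#' @return The tibble with every intensity `>= floor`.
#' @export
floor_intensities <- function(x, floor = 200) {
  x <- validate_expression_matrix(x)
  if (!is.numeric(floor) || length(floor) != 1 || floor <= 0) {
    abort("'floor' must be a single positive number")
  }
  dplyr::mutate(x, dplyr::across(-"mir_id", ~ pmax(.x, floor)))
}

#' Filter miRs by mean raw signal intensity
#'
#' Retains exactly the miRs whose mean raw intensity over the chosen samples
#' is at least `threshold`; miRs with mean signal under the threshold are
#' considered unreliably detected and removed before analysis. Row order is
#' preserved.
#'
#' @param x Expression tibble.
#' @param threshold Minimum mean intensity (default 200).
#' @param samples Character vector of sample ids over which the mean is taken;
#'   default all samples in `x`.
#' @return The filtered tibble.
#' @export
filter_by_mean <- function(x, threshold = 200, samples = NULL) {
  x <- validate_expression_matrix(x)
  if (is.null(samples)) samples <- names(x)[-1]
  if (length(samples) == 0) abort("'samples' must be non-empty")
  miss <- setdiff(samples, names(x)[-1])
  if (length(miss) > 0) {
    abort(paste0("unknown sample id(s): ", toString(miss)))
  }
  means <- rowMeans(as.matrix(x[samples]))
  out <- x[means >= threshold, ]
  if (nrow(out) == 0) {
    abort("mean-intensity filter removed every miR; nothing left to analyze")
  }
  out
}

#' Log-ratio normalize one (strain, treatment) time series
#'
#' For each miR and day, the normalized value is
#' `w = ln(max(x_day, floor) / max(x_naive, floor))`, with the strain's naive
#' sample as reference. The naive sample is included as the day-0 point of the
#' series (its own vector is identically zero), and a miR that never exceeds
#' the floor in any sample carries the value 0 at every day.
#'
#' @param x Expression tibble (raw intensities, already mean-filtered if
#'   desired).
#' @param sheet Sample sheet tibble.
#' @param strain,treatment The series to extract; `treatment` is `"sham"` or
#'   `"IRI"`.
#' @param floor Detection limit (default 200).
#' @return A tibble with columns `sample_id`, `strain`, `treatment`, `day`
#'   (ascending, day 0 = naive) followed by one numeric column per miR holding
#'   the natural-log ratio to the naive reference. The reference sample id is
#'   attached as attribute `reference_id`.
#' @export
normalize_series <- function(x, sheet, strain, treatment, floor = 200) {
  norm <- normalize_samples(x, sheet, floor = floor)
  extract_series(norm, strain, treatment)
}

#' Log-ratio normalize every sample against its strain's naive reference
#'
#' @inheritParams normalize_series
#' @return A tibble with one row per sample (columns `sample_id`, `strain`,
#'   `treatment`, `day`, then miRs), values `ln(max(x, floor)/max(ref, floor))`
#'   against the strain's naive sample.
#' @export
normalize_samples <- function(x, sheet, floor = 200) {
  x <- validate_expression_matrix(x)
  sheet <- validate_sample_sheet(sheet)
  sheet <- dplyr::filter(sheet, .data$sample_id %in% names(x)[-1])
  if (nrow(sheet) == 0) abort("no sample sheet rows match the matrix columns")
  mat <- pmax(as.matrix(x[-1]), floor) # miRs x samples
  rownames(mat) <- x$mir_id
  out <- purrr::map(split(sheet, sheet$strain), function(sh) {
    ref <- sh$sample_id[sh$treatment == "naive"]
    if (length(ref) != 1) {
      abort(paste0("strain '", sh$strain[1], "' needs exactly one naive ",
                   "reference sample, found ", length(ref)))
    }
    w <- t(log(mat[, sh$sample_id, drop = FALSE] / mat[, ref]))
    dplyr::bind_cols(
      dplyr::select(sh, dplyr::all_of(META_COLS)),
      tibble::as_tibble(w)
    )
  })
  out <- dplyr::bind_rows(out)
  refs <- sheet$sample_id[sheet$treatment == "naive"]
  structure(dplyr::arrange(out, .data$strain, .data$treatment, .data$day),
            reference_id = setNames(refs,
                                    sheet$strain[sheet$treatment == "naive"]))
}

#' Extract one (strain, treatment) series from a normalized table
#'
#' @param norm Normalized tibble from [normalize_samples()].
#' @param strain,treatment Series selector; the strain's naive day-0 row is
#'   always included.
#' @return Series tibble ordered by day, attribute `reference_id` set.
#' @export
extract_series <- function(norm, strain, treatment) {
  if (!treatment %in% c("sham", "IRI")) {
    abort("'treatment' must be \"sham\" or \"IRI\"")
  }
  rows <- dplyr::filter(norm, .data$strain == !!strain,
                        .data$treatment %in% c("naive", !!treatment))
  if (!any(rows$treatment == "naive")) {
    abort(paste0("no naive reference row for strain '", strain, "'"))
  }
  if (nrow(rows) < 2) {
    abort(paste0("series ", strain, "/", treatment, " has no treated samples"))
  }
  ref <- rows$sample_id[rows$treatment == "naive"]
  structure(dplyr::arrange(rows, .data$day), reference_id = ref)
}

#' Digitally knock out a set of miRs
#'
#' Sets the normalized (log-ratio) value of every miR in `mirs` to zero at
#' every time point, prior to PCA — as if those miRs never responded. All
#' other values are untouched.
#'
#' @param norm Normalized tibble ([normalize_samples()] or a series).
#' @param mirs Character vector of miR ids to silence; must all be present.
#' @return The tibble with the selected miR columns zeroed.
#' @export
digital_knockout <- function(norm, mirs) {
  if (length(mirs) == 0) return(norm)
  unknown <- setdiff(mirs, mir_cols(norm))
  if (length(unknown) > 0) {
    abort(paste0("unknown miR id(s) in knockout set: ", toString(unknown)))
  }
  att <- attr(norm, "reference_id")
  norm <- dplyr::mutate(norm, dplyr::across(dplyr::all_of(mirs), ~ 0))
  attr(norm, "reference_id") <- att
  norm
}

# miR columns of a normalized table
mir_cols <- function(norm) setdiff(names(norm), META_COLS)

# numeric matrix of miR values, rows = samples
mir_matrix <- function(norm) {
  m <- as.matrix(norm[mir_cols(norm)])
  rownames(m) <- norm$sample_id
  m
}
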