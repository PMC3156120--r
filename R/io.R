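#' Read an expression matrix from a tab-separated file
#'
#' The file must have a header row whose first field names the miR identifier
#' column (canonically `mir_id`) followed by one field per sample, and one row
#' per miR holding non-negative intensities in arbitrary fluorescence units.
#'
#' @param path Path to a TSV file.
#' @return A tibble with a `mir_id` character column followed by one numeric
#'   column per sample.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("mir_id\ts1\ts2", "miR-21\t500\t640", "miR-20a\t150\t210"), tf)
#' read_expression_matrix(tf)
#' @export
read_expression_matrix <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (length(hdr) == 0) abort(paste0("expression matrix '", path, "' is empty"))
  hdr <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 2) {
    abort(paste0("expression matrix '", path, "' needs a header with a miR id ",
                 "column plus at least one sample column"))
  }
  if (anyDuplicated(hdr)) {
    abort(paste0("expression matrix '", path, "': duplicate column ids: ",
                 toString(unique(hdr[duplicated(hdr)]))))
  }
  spec <- do.call(readr::cols,
                  c(setNames(list(readr::col_character()), hdr[1]),
                    list(.default = readr::col_double())))
  x <- suppressWarnings(
    readr::read_tsv(path, col_types = spec, progress = FALSE)
  )
  names(x)[1] <- "mir_id"
  validate_expression_matrix(x)
}

#' Read a GEO-style series matrix, stripping the metadata preamble
#'
#' Series-matrix exports carry `!`-prefixed metadata lines around the
#' tab-separated data block; this reads only the block between
#' `!series_matrix_table_begin` and `!series_matrix_table_end` (or, failing
#' those markers, all lines not starting with `!`).
#'
#' @inheritParams read_expression_matrix
#' @return A tibble as from [read_expression_matrix()].
#' @export
read_geo_series_matrix <- function(path) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  body <- if (length(beg) == 1 && length(end) == 1 && end > beg) {
    lines[(beg + 1):(end - 1)]
  } else {
    lines[!startsWith(lines, "!")]
  }
  body <- gsub("\"", "", body)
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf), add = TRUE)
  writeLines(body, tf)
  read_expression_matrix(tf)
}

#' Write an expression matrix to a tab-separated file
#'
#' @param x Expression tibble (`mir_id` + sample columns).
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  x <- validate_expression_matrix(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

validate_expression_matrix <- function(x, arg = "expression matrix") {
  x <- tibble::as_tibble(x)
  if (names(x)[1] != "mir_id") {
    abort(paste0(arg, ": first column must be 'mir_id'"))
  }
  if (anyDuplicated(x$mir_id)) {
    dup <- unique(x$mir_id[duplicated(x$mir_id)])
    abort(paste0(arg, ": duplicate miR ids: ", toString(utils::head(dup, 5))))
  }
  samp <- names(x)[-1]
  if (anyDuplicated(samp)) {
    abort(paste0(arg, ": duplicate sample ids: ",
                 toString(unique(samp[duplicated(samp)]))))
  }
  vals <- as.matrix(x[-1])
  if (!is.numeric(vals)) abort(paste0(arg, ": non-numeric intensity values"))
  bad <- which(!is.finite(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0(arg, ": negative or non-finite value at miR '",
                 x$mir_id[bad[1, 1]], "', sample '", samp[bad[1, 2]], "'"))
  }
  x
}

#' Read a sample sheet mapping samples to strain, treatment and day
#'
#' The sheet is tab-separated with header columns `sample_id`, `strain`,
#' `treatment` and `day`. Treatments must be one of `naive`, `sham` or `IRI`;
#' the single naive sample of each strain serves as that strain's day-0
#' reference for both treatment arms.
#'
#' @param path Path to a TSV file.
#' @return A validated tibble with columns `sample_id`, `strain`, `treatment`
#'   (factor-free character) and integer `day`.
#' @export
read_sample_sheet <- function(path) {
  x <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(
      sample_id = readr::col_character(),
      strain = readr::col_character(),
      treatment = readr::col_character(),
      day = readr::col_integer()
    ), progress = FALSE),
    error = function(e) abort(paste0("sample sheet '", path, "': ",
                                     conditionMessage(e)))
  )
  if (nrow(x) == 0) abort(paste0("sample sheet '", path, "' is empty"))
  validate_sample_sheet(x)
}

validate_sample_sheet <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("sample_id", "strain", "treatment", "day")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("sample sheet: missing columns: ", toString(miss)))
  }
  if (nrow(x) == 0) abort("sample sheet: no samples")
  if (anyDuplicated(x$sample_id)) {
    abort(paste0("sample sheet: duplicate sample ids: ",
                 toString(unique(x$sample_id[duplicated(x$sample_id)]))))
  }
  bad <- setdiff(unique(x$treatment), TREATMENTS)
  if (length(bad) > 0) {
    abort(paste0("sample sheet: unknown treatment label(s): ", toString(bad),
                 " (expected ", toString(TREATMENTS), ")"))
  }
  if (any(!is.finite(x$day)) || any(x$day < 0)) {
    abort("sample sheet: days must be non-negative integers")
  }
  x$day <- as.integer(x$day)
  naive <- dplyr::filter(x, .data$treatment == "naive")
  multi <- naive$strain[duplicated(naive$strain)]
  if (length(multi) > 0) {
    abort(paste0("sample sheet: more than one naive sample for strain(s): ",
                 toString(unique(multi))))
  }
  dup_day <- x %>%
    dplyr::filter(.data$treatment != "naive") %>%
    dplyr::count(.data$strain, .data$treatment, .data$day) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup_day) > 0) {
    abort(paste0("sample sheet: repeated day within arm: ",
                 paste(dup_day$strain, dup_day$treatment, dup_day$day,
                       collapse = "; ")))
  }
  dplyr::select(x, dplyr::all_of(need))
}

#' Write a sample sheet to a tab-separated file
#'
#' @param x Sample sheet tibble.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_sample_sheet <- function(x, path) {
  x <- validate_sample_sheet(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

#' Write an analysis report to JSON
#'
#' Serializes the report produced by [run_analysis()] — enclosing-cap radii in
#' degrees, spherical standard deviations, discriminations, Monte-Carlo
#' P-values, replicate counts, the RNG seed and the echoed plan — so a run is
#' fully reproducible from its report.
#'
#' @param report A `mir_report` as returned by [run_analysis()].
#' @param path Output path for the JSON document.
#' @return `report`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "mir_report")) abort("not a mir_report object")
  out <- unclass(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(report)
}

#' Read back a JSON analysis report
#'
#' @param path Path written by [write_report()].
#' @return A `mir_report` list; tabular sections are restored as tibbles.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("groups", "pairs", "proximity", "projections")) {
    if (!is.null(x[[nm]]) && length(x[[nm]]) > 0) {
      x[[nm]] <- tibble::as_tibble(x[[nm]])
    }
  }
  structure(x, class = "mir_report")
}

#' Export PC coordinates of each time point for external plotting
#'
#' @param report A `mir_report` from [run_analysis()].
#' @param path Output TSV path; columns `series`, `day`, `pc1`..`pck`.
#' @return The coordinate tibble, invisibly.
#' @export
write_pc_coordinates <- function(report, path) {
  if (!inherits(report, "mir_report")) abort("not a mir_report object")
  proj <- report$projections
  if (is.null(proj)) abort("report carries no projections")
  readr::write_tsv(proj, path, progress = FALSE)
  invisible(proj)
}
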