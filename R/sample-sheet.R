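#' Validate a newborn sample sheet
#'
#' A sample sheet is a tibble with one row per newborn and the clinical
#' fields the clock workflow needs:
#'
#' * `sample_id` — unique identifier, matching beta-matrix columns.
#' * `ga_ultrasound_days` — clinically estimated gestational age (GA) in
#'   whole days, from the routine ultrasound; must be positive.
#' * `art` — logical; `TRUE` for children conceived by assisted reproduction
#'   (IVF/ICSI). Intrauterine insemination counts as non-ART.
#' * `procedure` — `"IVF"`, `"ICSI"` or `"none"` (non-ART).
#' * `embryo_state` — `"fresh"`, `"frozen"` or `"none"` (non-ART).
#' * `birth_date` — calendar date of birth (`Date` or ISO-8601 string).
#' * `egg_retrieval_date`, `embryo_insertion_date`, `freeze_date` —
#'   ART procedure dates, `NA` where unknown or not applicable.
#' * `ga_etd_days` — embryo-transfer-date GA estimate in days; filled by
#'   [annotate_etd()], `NA` otherwise.
#'
#' ART-specific fields must be `"none"`/`NA` on non-ART rows, and any dates
#' present must respect egg retrieval <= freezing <= embryo insertion <=
#' birth.
#'
#' @param sheet a data frame with the columns above (missing optional
#'   columns are added as `NA`).
#' @return The validated sheet as a tibble, with date columns as `Date`.
#' @export
as_sample_sheet <- function(sheet) {
  sheet <- tibble::as_tibble(sheet)
  required <- c("sample_id", "ga_ultrasound_days", "art")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols) > 0) {
    stop("sample sheet lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  optional <- c(procedure = "none", embryo_state = "none")
  for (nm in names(optional)) {
    if (!nm %in% names(sheet)) sheet[[nm]] <- optional[[nm]]
  }
  date_cols <- c("birth_date", "egg_retrieval_date", "embryo_insertion_date",
                 "freeze_date")
  for (nm in date_cols) {
    if (!nm %in% names(sheet)) sheet[[nm]] <- as.Date(NA)
    sheet[[nm]] <- as.Date(sheet[[nm]])
  }
  if (!"ga_etd_days" %in% names(sheet)) sheet$ga_etd_days <- NA_integer_
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$art <- as.logical(sheet$art)
  # GA arithmetic is in whole days
  sheet$ga_ultrasound_days <- as.integer(round(as.numeric(sheet$ga_ultrasound_days)))
  sheet$ga_etd_days <- as.integer(round(as.numeric(sheet$ga_etd_days)))

  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample ids in sample sheet", call. = FALSE)
  }
  if (any(is.na(sheet$art))) stop("`art` must be TRUE/FALSE", call. = FALSE)
  bad_ga <- !is.na(sheet$ga_ultrasound_days) & sheet$ga_ultrasound_days <= 0
  if (any(bad_ga)) {
    stop("non-positive ultrasound GA for: ",
         paste(sheet$sample_id[bad_ga], collapse = ", "), call. = FALSE)
  }
  if (!all(sheet$procedure %in% c("IVF", "ICSI", "none"))) {
    stop("`procedure` must be one of IVF, ICSI, none", call. = FALSE)
  }
  if (!all(sheet$embryo_state %in% c("fresh", "frozen", "none"))) {
    stop("`embryo_state` must be one of fresh, frozen, none", call. = FALSE)
  }
  non_art <- !sheet$art
  art_only <- c("egg_retrieval_date", "embryo_insertion_date", "freeze_date")
  leak <- non_art & (sheet$procedure != "none" | sheet$embryo_state != "none" |
                       Reduce(`|`, lapply(sheet[art_only], Negate(is.na))))
  if (any(leak)) {
    stop("ART-specific fields set on non-ART rows: ",
         paste(sheet$sample_id[leak], collapse = ", "), call. = FALSE)
  }
  check_date_order(sheet)
  sheet
}

check_date_order <- function(sheet) {
  pairs <- list(
    c("egg_retrieval_date", "freeze_date"),
    c("egg_retrieval_date", "embryo_insertion_date"),
    c("freeze_date", "embryo_insertion_date"),
    c("embryo_insertion_date", "birth_date"),
    c("egg_retrieval_date", "birth_date")
  )
  for (p in pairs) {
    a <- sheet[[p[1]]]; b <- sheet[[p[2]]]
    bad <- !is.na(a) & !is.na(b) & a > b
    if (any(bad)) {
      stop(sprintf("date order violated (%s after %s) for: %s", p[1], p[2],
                   paste(sheet$sample_id[bad], collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(sheet)
}

#' Read / write sample sheets as CSV
#'
#' Dates are stored as ISO-8601 strings; GA fields in integer days. Reading
#' validates the [as_sample_sheet()] schema.
#'
#' @param path file path.
#' @return `read_sample_sheet()` returns a validated tibble;
#'   `write_sample_sheet()` returns `path` invisibly.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_csv(path, na = c("", "NA"), progress = FALSE,
                        show_col_types = FALSE)
  as_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet a sample sheet tibble.
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet <- as_sample_sheet(sheet)
  readr::write_csv(sheet, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read / write probe annotations
#'
#' Probe annotations flag, per probe id, membership of the older 450K array
#' (`on_450k`), cross-reactive probes, probes whose last three bases overlap
#' a SNP (`snp_overlap`), and autosomal location. One row per probe.
#'
#' @param path CSV file path.
#' @return A tibble with columns `probe_id`, `on_450k`, `cross_reactive`,
#'   `snp_overlap`, `autosomal`.
#' @export
read_probe_annotation <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_probe_annotation(df)
}

#' @rdname read_probe_annotation
#' @param ann annotation tibble.
#' @export
write_probe_annotation <- function(ann, path) {
  readr::write_csv(as_probe_annotation(ann), path, progress = FALSE)
  invisible(path)
}

#' @rdname read_probe_annotation
#' @export
as_probe_annotation <- function(ann) {
  ann <- tibble::as_tibble(ann)
  needed <- c("probe_id", "on_450k", "cross_reactive", "snp_overlap",
              "autosomal")
  miss <- setdiff(needed, names(ann))
  if (length(miss) > 0) {
    stop("probe annotation lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ann$probe_id)) {
    stop("duplicate probe ids in annotation", call. = FALSE)
  }
  ann[needed]
}

#' Read / write plain-text probe-id lists (one id per line)
#'
#' @param path file path.
#' @return `read_probe_list()` returns a character vector.
#' @export
read_probe_list <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}

#' @rdname read_probe_list
#' @param ids character vector of probe ids.
#' @export
write_probe_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}
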