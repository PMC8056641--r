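#' Construct a beta-value matrix
#'
#' A `beta_matrix` holds methylation beta values (methylated / total signal,
#' bounded in \[0, 1\]) for a set of array probes measured across a set of
#' samples, stored probes-as-rows as methylation matrices are usually
#' distributed. An optional detection p-value grid of identical shape can be
#' attached; it is consumed by [filter_probes()].
#'
#' @param values numeric matrix, probes in rows and samples in columns, with
#'   rownames giving probe ids and colnames giving sample ids. `NA` cells mark
#'   failed or absent measurements; all non-missing values must lie in
#'   \[0, 1\].
#' @param detection_p optional numeric matrix of per-probe, per-sample
#'   detection p-values with the same dimensions and dimnames as `values`.
#' @return An object of class `beta_matrix`.
#' @examples
#' m <- matrix(c(0.1, 0.9, 0.5, 0.4), 2, 2,
#'             dimnames = list(c("cg01", "cg02"), c("s1", "s2")))
#' bm <- beta_matrix(m)
#' dim(bm)
#' @export
beta_matrix <- function(values, detection_p = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  validate_beta_values(values)
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    storage.mode(detection_p) <- "double"
    if (!identical(dim(detection_p), dim(values)) ||
        !identical(dimnames(detection_p), dimnames(values))) {
      stop("`detection_p` must have the same shape and dimnames as `values`",
           call. = FALSE)
    }
    bad <- which(!is.na(detection_p) & (detection_p < 0 | detection_p > 1))
    if (length(bad) > 0) {
      stop("detection p-values outside [0, 1]", call. = FALSE)
    }
  }
  structure(list(values = values, detection_p = detection_p),
            class = "beta_matrix")
}

validate_beta_values <- function(values) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("beta matrix needs probe ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    dups <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate probe ids: ", paste(utils::head(dups, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dups <- unique(colnames(values)[duplicated(colnames(values))])
    stop("duplicate sample ids: ", paste(utils::head(dups, 5), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "beta value %g outside [0, 1] at probe '%s', sample '%s' (%d offending cell%s)",
      values[i, j], rownames(values)[i], colnames(values)[j],
      nrow(bad), if (nrow(bad) == 1) "" else "s"), call. = FALSE)
  }
  invisible(values)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' @export
dimnames.beta_matrix <- function(x) dimnames(x$values)

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d probes x %d samples", nrow(x$values),
              ncol(x$values)))
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat(sprintf(", %d missing cells", n_na))
  if (!is.null(x$detection_p)) cat(", with detection p-values")
  cat("\n")
  invisible(x)
}

#' Probe and sample accessors
#'
#' @param bm a [beta_matrix()].
#' @return Character vectors of probe or sample ids.
#' @export
probe_ids <- function(bm) rownames(bm$values)

#' @rdname probe_ids
#' @export
sample_ids <- function(bm) colnames(bm$values)

#' Subset a beta matrix by probe and/or sample ids
#'
#' @param bm a [beta_matrix()].
#' @param probes,samples character vectors of ids to keep (in the stored
#'   order); `NULL` keeps all.
#' @return A `beta_matrix`.
#' @export
subset_beta <- function(bm, probes = NULL, samples = NULL) {
  keep_p <- if (is.null(probes)) rownames(bm$values) else
    intersect(rownames(bm$values), probes)
  keep_s <- if (is.null(samples)) colnames(bm$values) else
    intersect(colnames(bm$values), samples)
  if (length(keep_p) == 0) stop("no probes left after subsetting", call. = FALSE)
  if (length(keep_s) == 0) stop("no samples left after subsetting", call. = FALSE)
  beta_matrix(bm$values[keep_p, keep_s, drop = FALSE],
              detection_p = if (is.null(bm$detection_p)) NULL else
                bm$detection_p[keep_p, keep_s, drop = FALSE])
}

#' Transpose to the samples-by-probes orientation
#'
#' Clock fitting works on an n-samples-by-p-probes design matrix; storage is
#' probes-as-rows. `beta_design()` returns the transposed numeric matrix.
#'
#' @param bm a [beta_matrix()].
#' @return A samples x probes numeric matrix.
#' @export
beta_design <- function(bm) t(bm$values)

#' Read / write beta matrices as TSV
#'
#' The TSV has one header row of sample ids and a first column of probe ids
#' (orientation `"probes_rows"`, the default), or the transpose
#' (`"samples_rows"`). Empty cells and `NA` are read as missing.
#'
#' @param path file path.
#' @param orientation `"probes_rows"` or `"samples_rows"`.
#' @param detection_p_path optional path to a detection p-value TSV with the
#'   same layout.
#' @return `read_beta_matrix()` returns a [beta_matrix()];
#'   `write_beta_matrix()` returns `path` invisibly.
#' @export
read_beta_matrix <- function(path, orientation = c("probes_rows", "samples_rows"),
                             detection_p_path = NULL) {
  orientation <- match.arg(orientation)
  values <- read_id_matrix(path)
  if (orientation == "samples_rows") values <- t(values)
  detp <- NULL
  if (!is.null(detection_p_path)) {
    detp <- read_id_matrix(detection_p_path)
    if (orientation == "samples_rows") detp <- t(detp)
    detp <- detp[rownames(values), colnames(values), drop = FALSE]
  }
  beta_matrix(values, detection_p = detp)
}

read_id_matrix <- function(path) {
  # columns come in as text and go through base as.numeric(): the usual
  # fast float parsers are not correctly rounded, and round-trips must be
  df <- readr::read_tsv(path, na = c("", "NA"), progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  ids <- as.character(df[[1]])
  df[-1] <- lapply(df[-1], as.numeric)
  if (anyDuplicated(ids)) {
    stop("duplicate row ids in ", path, call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  m
}

#' @rdname read_beta_matrix
#' @param bm a [beta_matrix()] to write.
#' @export
write_beta_matrix <- function(bm, path,
                              orientation = c("probes_rows", "samples_rows"),
                              detection_p_path = NULL) {
  orientation <- match.arg(orientation)
  write_id_matrix(bm$values, path, orientation, id_col = "probe_id")
  if (!is.null(detection_p_path) && !is.null(bm$detection_p)) {
    write_id_matrix(bm$detection_p, detection_p_path, orientation,
                    id_col = "probe_id")
  }
  invisible(path)
}

write_id_matrix <- function(m, path, orientation, id_col) {
  if (orientation == "samples_rows") {
    m <- t(m)
    id_col <- "sample_id"
  }
  df <- fmt_doubles(tibble::as_tibble(m, rownames = id_col))
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

# Render double columns with 17 significant digits so that numeric text
# files round-trip bit-exactly.
fmt_doubles <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      out <- sprintf("%.17g", df[[nm]])
      out[is.na(df[[nm]])] <- NA_character_
      df[[nm]] <- out
    }
  }
  df
}

#' Tidy a beta matrix into long format
#'
#' @param x a [beta_matrix()].
#' @param ... unused.
#' @return A tibble with columns `probe_id`, `sample_id`, `beta`.
#' @export
tidy.beta_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "probe_id") |>
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id",
                        values_to = "beta")
}
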