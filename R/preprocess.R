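#' Filter probes by quality-control flags
#'
#' Removes probes in a fixed order — cross-reactive, detection p-value
#' failures, SNP-overlapping, non-autosomal — so that stage counts are
#' deterministic, and reports the number removed at each stage.
#'
#' A probe fails detection when its detection p-value exceeds
#' `detection_p_threshold`. By default one failing sample is enough to
#' remove the probe; setting `detp_fraction = f` (0 < f <= 1) instead
#' removes a probe failing in at least a fraction `f` of samples, e.g.
#' `f = 0.25` for the "at least 25% of samples" dialect some cohorts use.
#' Probes with no detection p-values attached never fail this stage.
#'
#' @param bm a [beta_matrix()] (attach detection p-values via
#'   [beta_matrix()] or [read_beta_matrix()]).
#' @param ann probe annotation covering every probe in `bm`
#'   ([as_probe_annotation()] schema).
#' @param detection_p_threshold detection p-value above which a measurement
#'   fails; in (0, 1].
#' @param detp_fraction `NULL` (any failing sample removes the probe) or a
#'   fraction in (0, 1\]: the probe is removed when at least this fraction
#'   of samples fails.
#' @param drop_cross_reactive,drop_snp_overlap,autosomal_only stage switches.
#' @return A list with `beta` (the filtered [beta_matrix()]) and `report`, a
#'   tibble with one row per stage (`stage`, `n_removed`, `n_remaining`).
#' @export
filter_probes <- function(bm, ann, detection_p_threshold = 0.01,
                          detp_fraction = NULL, drop_cross_reactive = TRUE,
                          drop_snp_overlap = TRUE, autosomal_only = TRUE) {
  stopifnot(inherits(bm, "beta_matrix"))
  ann <- as_probe_annotation(ann)
  if (detection_p_threshold <= 0 || detection_p_threshold > 1) {
    stop("`detection_p_threshold` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(detp_fraction) &&
      (detp_fraction <= 0 || detp_fraction > 1)) {
    stop("`detp_fraction` must lie in (0, 1]", call. = FALSE)
  }
  probes <- probe_ids(bm)
  unknown <- setdiff(probes, ann$probe_id)
  if (length(unknown) > 0) {
    stop("probes missing from annotation: ",
         paste(utils::head(unknown, 10), collapse = ", "),
         if (length(unknown) > 10) sprintf(" (and %d more)", length(unknown) - 10),
         call. = FALSE)
  }
  ann <- ann[match(probes, ann$probe_id), ]

  keep <- rep(TRUE, length(probes))
  removed <- integer(4)

  if (drop_cross_reactive) {
    drop <- keep & ann$cross_reactive
    removed[1] <- sum(drop)
    keep <- keep & !drop
  }
  if (!is.null(bm$detection_p)) {
    fail_frac <- rowMeans(bm$detection_p > detection_p_threshold, na.rm = TRUE)
    fail_frac[is.nan(fail_frac)] <- 0
    drop <- keep & if (is.null(detp_fraction)) fail_frac > 0 else
      fail_frac >= detp_fraction
    removed[2] <- sum(drop)
    keep <- keep & !drop
  }
  if (drop_snp_overlap) {
    drop <- keep & ann$snp_overlap
    removed[3] <- sum(drop)
    keep <- keep & !drop
  }
  if (autosomal_only) {
    drop <- keep & !ann$autosomal
    removed[4] <- sum(drop)
    keep <- keep & !drop
  }

  kept_ids <- probes[keep]
  if (length(kept_ids) == 0) stop("all probes removed by filtering", call. = FALSE)
  report <- tibble::tibble(
    stage = c("cross_reactive", "detection_p", "snp_overlap", "non_autosomal"),
    n_removed = removed,
    n_remaining = length(probes) - cumsum(removed)
  )
  list(beta = subset_beta(bm, probes = kept_ids), report = report)
}

#' Restrict a beta matrix to a platform probe set
#'
#' Keeps the intersection of the matrix probes and `probe_set`, preserving
#' the matrix order — e.g. the ~397K CpGs shared between the 450K and EPIC
#' arrays when building a cross-platform clock.
#'
#' @param bm a [beta_matrix()].
#' @param probe_set character vector of probe ids defining the platform.
#' @return A [beta_matrix()].
#' @export
restrict_to_platform <- function(bm, probe_set) {
  stopifnot(inherits(bm, "beta_matrix"))
  kept <- intersect(probe_ids(bm), probe_set)
  if (length(kept) == 0) {
    stop("no probes in common with the platform set", call. = FALSE)
  }
  subset_beta(bm, probes = kept)
}

#' Median-impute missing beta values
#'
#' Each missing cell is replaced by the median of that probe's non-missing
#' values across samples. A probe with no observed values at all falls back
#' to `fallback_medians` (typically a clock's training medians); without a
#' fallback such probes are an error.
#'
#' @param bm a [beta_matrix()].
#' @param fallback_medians optional named numeric vector, probe id -> beta.
#' @return A [beta_matrix()] with no missing values; non-missing cells are
#'   untouched.
#' @export
impute_missing <- function(bm, fallback_medians = NULL) {
  stopifnot(inherits(bm, "beta_matrix"))
  v <- bm$values
  miss <- is.na(v)
  if (!any(miss)) return(bm)
  med <- apply(v, 1, stats::median, na.rm = TRUE)
  all_missing <- is.nan(med) | is.na(med)
  if (any(all_missing)) {
    ids <- rownames(v)[all_missing]
    if (is.null(fallback_medians)) {
      stop("probes with no observed values and no fallback medians: ",
           paste(utils::head(ids, 10), collapse = ", "), call. = FALSE)
    }
    have <- ids %in% names(fallback_medians)
    if (!all(have)) {
      stop("probes with no observed values and no fallback medians: ",
           paste(utils::head(ids[!have], 10), collapse = ", "), call. = FALSE)
    }
    med[all_missing] <- fallback_medians[ids]
  }
  idx <- which(miss, arr.ind = TRUE)
  v[miss] <- med[idx[, 1]]
  beta_matrix(v, detection_p = bm$detection_p)
}
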