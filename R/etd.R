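#' Gestational age from embryo-transfer dates
#'
#' For ART-conceived children the procedure dates give an independent GA
#' estimate (the embryo-transfer-date, ETD, estimate), by analogy with the
#' 14 days conventionally separating the last menstrual period from
#' conception:
#'
#' * fresh transfer, egg retrieval date known:
#'   `GA = (birth - retrieval) + 14`;
#' * fresh transfer, retrieval unknown: the insertion date stands in for
#'   retrieval minus the two days a fresh embryo is cultured,
#'   `GA = (birth - (insertion - 2)) + 14`;
#' * frozen transfer: `GA = (birth - insertion) + 14 +
#'   (freeze - retrieval)`, crediting the embryo the days it developed
#'   before freezing.
#'
#' All arithmetic is in whole days. Intrauterine insemination counts as
#' non-ART and is rejected.
#'
#' @param rec a single sample record: a one-row data frame (or list) with
#'   the [as_sample_sheet()] date and ART fields.
#' @return Integer gestational age in days.
#' @examples
#' compute_etd_ga(list(art = TRUE, embryo_state = "fresh",
#'                     egg_retrieval_date = as.Date("2010-01-01"),
#'                     birth_date = as.Date("2010-09-23")))  # 279
#' @export
compute_etd_ga <- function(rec) {
  if (is.data.frame(rec)) {
    if (nrow(rec) != 1) stop("`rec` must be a single record", call. = FALSE)
    rec <- as.list(rec)
  }
  get_date <- function(nm) {
    v <- rec[[nm]]
    if (is.null(v) || all(is.na(v))) return(as.Date(NA))
    as.Date(v)
  }
  if (is.null(rec$art) || is.na(rec$art) || !rec$art) {
    stop("ETD gestational age is defined for ART records only", call. = FALSE)
  }
  birth <- get_date("birth_date")
  if (is.na(birth)) stop("missing birth_date", call. = FALSE)
  retrieval <- get_date("egg_retrieval_date")
  insertion <- get_date("embryo_insertion_date")
  freeze <- get_date("freeze_date")
  frozen <- identical(rec$embryo_state, "frozen")

  ga <- if (frozen) {
    need <- c(embryo_insertion_date = is.na(insertion),
              freeze_date = is.na(freeze),
              egg_retrieval_date = is.na(retrieval))
    if (any(need)) {
      stop("frozen-transfer record missing: ",
           paste(names(need)[need], collapse = ", "), call. = FALSE)
    }
    as.integer(birth - insertion) + 14L + as.integer(freeze - retrieval)
  } else if (!is.na(retrieval)) {
    as.integer(birth - retrieval) + 14L
  } else if (!is.na(insertion)) {
    as.integer(birth - (insertion - 2L)) + 14L
  } else {
    stop("fresh-transfer record missing egg_retrieval_date and ",
         "embryo_insertion_date", call. = FALSE)
  }
  if (ga <= 0) stop("non-positive ETD gestational age (", ga, " days)",
                    call. = FALSE)
  ga
}

#' Annotate a sample sheet with ETD gestational ages
#'
#' Fills `ga_etd_days` for every ART record whose dates suffice, leaves
#' other records untouched, and attaches a per-rule report. Records whose
#' dates are insufficient are flagged in the report rather than failing the
#' whole sheet.
#'
#' @param sheet a sample sheet ([as_sample_sheet()] schema).
#' @return The sheet with `ga_etd_days` filled where possible; attribute
#'   `"etd_report"` holds a tibble with one row per ART record (`sample_id`,
#'   `rule` — one of `fresh_retrieval`, `fresh_insertion`, `frozen`,
#'   `failed` — and `message` for failures).
#' @export
annotate_etd <- function(sheet) {
  sheet <- as_sample_sheet(sheet)
  art_idx <- which(sheet$art)
  rows <- vector("list", length(art_idx))
  for (k in seq_along(art_idx)) {
    i <- art_idx[k]
    rec <- as.list(sheet[i, ])
    rule <- if (identical(rec$embryo_state, "frozen")) "frozen"
      else if (!is.na(rec$egg_retrieval_date)) "fresh_retrieval"
      else "fresh_insertion"
    res <- tryCatch(compute_etd_ga(rec), error = function(e) e)
    if (inherits(res, "error")) {
      rows[[k]] <- tibble::tibble(sample_id = rec$sample_id, rule = "failed",
                                  message = conditionMessage(res))
    } else {
      sheet$ga_etd_days[i] <- res
      rows[[k]] <- tibble::tibble(sample_id = rec$sample_id, rule = rule,
                                  message = NA_character_)
    }
  }
  attr(sheet, "etd_report") <- dplyr::bind_rows(rows)
  sheet
}
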