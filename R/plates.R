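#' @importFrom rlang .data :=
#' @importFrom dplyr %>%
NULL

# Canonical long-format plate columns. A format_spec (list or YAML file) may
# map arbitrary input column names onto these.
PLATE_COLUMNS <- c("plate_id", "well", "role", "sample_id", "dilution",
                   "replicate", "abs_0h", "abs_12h")

WELL_ROLES <- c("SAMPLE", "POSITIVE_CONTROL", "NEGATIVE_CONTROL")

#' Serial-dilution denominators eligible for rank scoring
#'
#' The endpoint scoring scale covers the two-fold serial dilutions 1:2 to
#' 1:256. Fine-grained dilutions (e.g. 1:70, 1:80, 1:90) may appear on plates
#' for capacity measurement but are never ranked.
#' @export
RANKED_DILUTIONS <- c(2, 4, 8, 16, 32, 64, 128, 256)

#' Map a serial-dilution denominator to its rank index
#'
#' Dilution 1:2 corresponds to rank index 1, 1:4 to rank index 2, and so on
#' up to 1:256 at rank index 8 (i.e. `log2(denominator)`).
#'
#' @param denominator Integer vector of dilution denominators; each must be a
#'   power of two in 2..256. Fine-grained dilutions such as 70, 80, 90 are
#'   capacity-only and rejected here.
#' @return Integer vector of rank indices in 1..8.
#' @examples
#' dilution_to_rank_index(c(2, 4, 256))
#' @export
dilution_to_rank_index <- function(denominator) {
  if (!all(denominator %in% RANKED_DILUTIONS)) {
    bad <- unique(denominator[!denominator %in% RANKED_DILUTIONS])
    stop("dilution denominator(s) not on the ranked 1:2..1:256 scale: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  as.integer(log2(denominator))
}

resolve_format_spec <- function(format_spec) {
  if (is.null(format_spec)) return(stats::setNames(PLATE_COLUMNS, PLATE_COLUMNS))
  if (is.character(format_spec) && length(format_spec) == 1) {
    format_spec <- yaml::read_yaml(format_spec)
  }
  if (!is.null(format_spec$columns)) format_spec <- format_spec$columns
  map <- stats::setNames(PLATE_COLUMNS, PLATE_COLUMNS)
  for (canon in names(format_spec)) {
    if (!canon %in% PLATE_COLUMNS) {
      stop("format_spec maps unknown canonical column '", canon, "'",
           call. = FALSE)
    }
    map[canon] <- format_spec[[canon]]
  }
  map
}

#' Read and validate a plate-reader table
#'
#' Reads a long-format CSV/TSV of well readings (one row per well) and
#' validates it into a plate table: roles checked, sample wells required to
#' carry a dilution and sample id, absorbances non-negative, well labels
#' unique within a plate, and at least one negative and one positive control
#' per plate. Row order is irrelevant; grouping is by
#' (sample_id, dilution, replicate), never by physical well position.
#'
#' @param path Path to a delimited text file.
#' @param format_spec Optional column mapping: a named list (or path to a
#'   YAML file, possibly under a top-level `columns:` key) mapping canonical
#'   names (`plate_id`, `well`, `role`, `sample_id`, `dilution`, `replicate`,
#'   `abs_0h`, `abs_12h`) to the file's column names.
#' @param delim Field delimiter, `","` by default.
#' @return A tibble of class `bka_plate` with the canonical columns.
#' @export
read_plate_table <- function(path, format_spec = NULL, delim = ",") {
  if (!file.exists(path)) stop("plate file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  map <- resolve_format_spec(format_spec)
  missing <- map[!map %in% names(raw)]
  if (length(missing) > 0) {
    stop("plate table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl <- tibble::tibble(
    plate_id  = as.character(raw[[map["plate_id"]]]),
    well      = as.character(raw[[map["well"]]]),
    role      = toupper(as.character(raw[[map["role"]]])),
    sample_id = as.character(raw[[map["sample_id"]]]),
    dilution  = suppressWarnings(as.numeric(raw[[map["dilution"]]])),
    replicate = suppressWarnings(as.integer(raw[[map["replicate"]]])),
    abs_0h    = as.numeric(raw[[map["abs_0h"]]]),
    abs_12h   = as.numeric(raw[[map["abs_12h"]]])
  )
  as_bka_plate(tbl)
}

#' Validate a well table as a plate
#'
#' @param tbl Data frame with the canonical plate columns.
#' @return The validated tibble with class `bka_plate`.
#' @export
as_bka_plate <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  missing <- setdiff(PLATE_COLUMNS, names(tbl))
  if (length(missing) > 0) {
    stop("plate table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl <- tbl[PLATE_COLUMNS]
  if (!all(tbl$role %in% WELL_ROLES)) {
    stop("unknown well role(s): ",
         paste(setdiff(unique(tbl$role), WELL_ROLES), collapse = ", "),
         call. = FALSE)
  }
  is_sample <- tbl$role == "SAMPLE"
  if (any(is_sample & (is.na(tbl$dilution)))) {
    stop("SAMPLE well(s) missing dilution denominator", call. = FALSE)
  }
  if (any(is_sample & (is.na(tbl$sample_id) | tbl$sample_id == ""))) {
    stop("SAMPLE well(s) missing sample_id", call. = FALSE)
  }
  if (any(is.na(tbl$abs_0h) | is.na(tbl$abs_12h) |
          tbl$abs_0h < 0 | tbl$abs_12h < 0)) {
    stop("absorbances must be present and non-negative", call. = FALSE)
  }
  dup <- tbl %>%
    dplyr::count(.data$plate_id, .data$well) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate well label(s) on plate ",
         paste(unique(dup$plate_id), collapse = ", "), ": ",
         paste(utils::head(dup$well, 5), collapse = ", "), call. = FALSE)
  }
  ctl <- tbl %>%
    dplyr::group_by(.data$plate_id) %>%
    dplyr::summarise(
      n_neg = sum(.data$role == "NEGATIVE_CONTROL"),
      n_pos = sum(.data$role == "POSITIVE_CONTROL"),
      .groups = "drop"
    )
  if (any(ctl$n_neg < 1) || any(ctl$n_pos < 1)) {
    bad <- ctl$plate_id[ctl$n_neg < 1 | ctl$n_pos < 1]
    stop("plate(s) without both control types: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  class(tbl) <- c("bka_plate", class(tibble::tibble()))
  tbl
}

#' Write a plate table to canonical long-format CSV
#'
#' @param plate A `bka_plate` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(plate, path) {
  plate <- as_bka_plate(plate)
  readr::write_csv(plate, path, progress = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Metadata links each serum sample to its individual, species, sex,
#' and sampling year; `storage_years` is the time from sampling to assay.
#'
#' @param path CSV with columns `sample_id`, `individual_id`, `species`,
#'   `sex`, `sampling_year` and optionally `storage_years`.
#' @return A validated tibble.
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_meta(meta)
}

#' @rdname read_sample_meta
#' @param meta A metadata data frame to validate.
#' @export
validate_sample_meta <- function(meta) {
  meta <- tibble::as_tibble(meta)
  need <- c("sample_id", "individual_id", "species", "sex", "sampling_year")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0) {
    stop("metadata missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"storage_years" %in% names(meta)) meta$storage_years <- NA_real_
  meta$sex <- toupper(as.character(meta$sex))
  if (!all(meta$sex %in% c("M", "F", "UNKNOWN"))) {
    stop("sex must be one of M, F, UNKNOWN", call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id(s) in metadata: ",
         paste(utils::head(unique(meta$sample_id[duplicated(meta$sample_id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(meta$storage_years) & meta$storage_years < 0)) {
    stop("storage_years must be non-negative", call. = FALSE)
  }
  meta
}
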