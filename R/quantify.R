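# Plate-level quantification: background-drift correction and percent
# killing capacity relative to the serum-free positive control.

#' Plate background-drift correction from negative controls
#'
#' The growth medium can discolour over the 12 h incubation, dropping
#' negative-control absorbance by up to ~14%. The correction term is the
#' mean over the plate's own negative controls of (abs_12h - abs_0h); it is
#' typically negative (discolouration) or zero, and is estimated per plate,
#' never pooled across plates.
#'
#' @param plate A `bka_plate` (single plate; if several plate ids are
#'   present an error is raised — correct each plate separately).
#' @param drift_warn_fraction Warn if `|delta_C|` exceeds this fraction of
#'   the mean negative-control abs_0h (default 0.14).
#' @return A list with `delta_C` (signed absorbance) and `n_negative`.
#' @export
compute_delta_C <- function(plate, drift_warn_fraction = 0.14) {
  plate <- as_bka_plate(plate)
  if (length(unique(plate$plate_id)) != 1) {
    stop("compute_delta_C expects a single plate; got ",
         length(unique(plate$plate_id)), call. = FALSE)
  }
  neg <- plate[plate$role == "NEGATIVE_CONTROL", ]
  if (nrow(neg) < 1) stop("plate has no negative controls", call. = FALSE)
  delta_C <- mean(neg$abs_12h - neg$abs_0h)
  base <- mean(neg$abs_0h)
  if (base > 0 && abs(delta_C) > drift_warn_fraction * base) {
    warning(sprintf(
      "plate %s: |delta_C| = %.3f exceeds %.0f%% of negative-control abs_0h",
      plate$plate_id[1], abs(delta_C), 100 * drift_warn_fraction),
      call. = FALSE)
  }
  list(delta_C = delta_C, n_negative = nrow(neg))
}

#' Drift-corrected absorbance growth of a well
#'
#' The raw growth of a well is abs_12h - abs_0h. Under the `"add"` sign
#' convention the plate correction `delta_C` is added to each raw growth;
#' under `"subtract"` it is subtracted. Both conventions are exposed because
#' the direction that cancels (rather than doubles) a shared medium drift in
#' sample wells is the subtractive one, while the additive one follows the
#' assay's published description verbatim; with no drift they coincide.
#'
#' @param abs_0h,abs_12h Absorbances at the two timepoints (vectors).
#' @param delta_C Plate correction from [compute_delta_C()].
#' @param sign_convention `"add"` (default) or `"subtract"`.
#' @return Signed corrected growth (absorbance units).
#' @export
corrected_growth <- function(abs_0h, abs_12h, delta_C,
                             sign_convention = c("add", "subtract")) {
  sign_convention <- match.arg(sign_convention)
  raw <- abs_12h - abs_0h
  if (sign_convention == "add") raw + delta_C else raw - delta_C
}

#' Percent bacterial killing capacity
#'
#' Capacity is `(1 - oD / oP) * 100`, where `oD` is the (mean) corrected
#' growth of the serum wells at a dilution and `oP` the mean growth of the
#' serum-free positive controls. Values above 100% (net absorbance loss) or
#' below 0% (growth exceeding the positive control) are retained unless
#' `clip = TRUE`.
#'
#' @param oD Signed mean corrected growth (vector).
#' @param oP Positive-control mean growth; must be > 0.
#' @param clip Clip results into \[0, 100\]? Default `FALSE`.
#' @return Percent killing capacity.
#' @export
killing_capacity <- function(oD, oP, clip = FALSE) {
  if (!is.finite(oP) || oP <= 0) {
    stop("positive-control mean growth must be > 0 (plate invalid); got ",
         format(oP), call. = FALSE)
  }
  cap <- (1 - oD / oP) * 100
  if (clip) cap <- pmin(pmax(cap, 0), 100)
  cap
}

#' Quantify killing capacities for every sample on a plate
#'
#' Applies the plate's negative-control drift correction to every
#' bacteria-bearing well, computes the positive-control mean growth, then
#' per-well capacities and their per-dilution means (duplicates averaged).
#'
#' @param plate A `bka_plate` for one plate.
#' @param sign_convention Drift-correction convention, see
#'   [corrected_growth()].
#' @param positive_mode `"corrected"` (default): the positive-control mean
#'   is the mean drift-corrected growth of the positive wells.
#'   `"raw_12h"`: the mean raw 12 h absorbance of the positive wells.
#' @param clip Clip capacities to \[0, 100\]? Default `FALSE`.
#' @param strict Error (instead of warn) when a sample has a number of
#'   replicates other than 2 at some dilution.
#' @return A tibble of class `bka_capacity` with one row per
#'   sample x dilution: `sample_id`, `dilution`, `rank_index` (NA for
#'   fine-grained dilutions), `n_rep`, `rep_capacities` (list column),
#'   `mean_capacity`, plus plate-level `plate_id`, `delta_C`, `oP`.
#' @export
quantify_plate <- function(plate, sign_convention = c("add", "subtract"),
                           positive_mode = c("corrected", "raw_12h"),
                           clip = FALSE, strict = FALSE) {
  plate <- as_bka_plate(plate)
  sign_convention <- match.arg(sign_convention)
  positive_mode <- match.arg(positive_mode)
  if (length(unique(plate$plate_id)) != 1) {
    stop("quantify_plate expects a single plate", call. = FALSE)
  }
  corr <- compute_delta_C(plate)
  pos <- plate[plate$role == "POSITIVE_CONTROL", ]
  oP <- switch(positive_mode,
    corrected = mean(corrected_growth(pos$abs_0h, pos$abs_12h, corr$delta_C,
                                      sign_convention)),
    raw_12h = mean(pos$abs_12h)
  )
  if (!is.finite(oP) || oP <= 0) {
    stop("plate ", plate$plate_id[1],
         ": positive-control mean growth not > 0 (", format(oP), ")",
         call. = FALSE)
  }
  smp <- plate[plate$role == "SAMPLE", ]
  smp$dA <- corrected_growth(smp$abs_0h, smp$abs_12h, corr$delta_C,
                             sign_convention)
  smp$capacity <- killing_capacity(smp$dA, oP, clip = clip)

  out <- smp %>%
    dplyr::group_by(.data$sample_id, .data$dilution) %>%
    dplyr::summarise(
      n_rep = dplyr::n(),
      rep_capacities = list(.data$capacity[order(.data$replicate)]),
      mean_capacity = mean(.data$capacity),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$sample_id, .data$dilution)
  odd <- out$n_rep != 2
  if (any(odd)) {
    msg <- sprintf("%d sample x dilution cell(s) with != 2 replicates",
                   sum(odd))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  out$rank_index <- ifelse(out$dilution %in% RANKED_DILUTIONS,
                           as.integer(log2(out$dilution)), NA_integer_)
  out$plate_id <- plate$plate_id[1]
  out$delta_C <- corr$delta_C
  out$oP <- oP
  out <- out[, c("plate_id", "sample_id", "dilution", "rank_index", "n_rep",
                 "rep_capacities", "mean_capacity", "delta_C", "oP")]
  class(out) <- c("bka_capacity", class(tibble::tibble()))
  out
}

#' Quantify a set of plates
#'
#' @param plates A `bka_plate` table possibly holding several plates, or a
#'   list of single-plate tables.
#' @inheritParams quantify_plate
#' @return A combined `bka_capacity` tibble.
#' @export
quantify_plates <- function(plates, sign_convention = c("add", "subtract"),
                            positive_mode = c("corrected", "raw_12h"),
                            clip = FALSE, strict = FALSE) {
  sign_convention <- match.arg(sign_convention)
  positive_mode <- match.arg(positive_mode)
  if (is.data.frame(plates)) {
    plates <- split(tibble::as_tibble(plates), plates$plate_id)
  }
  out <- purrr::map(plates, function(p) {
    quantify_plate(as_bka_plate(p), sign_convention = sign_convention,
                   positive_mode = positive_mode, clip = clip,
                   strict = strict)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("bka_capacity", class(tibble::tibble()))
  out
}

#' Export a capacity table as flat CSV
#'
#' One row per sample x dilution with the duplicate capacities unpacked into
#' `rep1_capacity`, `rep2_capacity`.
#'
#' @param capacities A `bka_capacity` tibble.
#' @param path Optional output CSV path.
#' @return The flat tibble (invisibly written to `path` if given).
#' @export
capacity_table <- function(capacities, path = NULL) {
  flat <- capacities %>%
    dplyr::mutate(
      rep1_capacity = purrr::map_dbl(.data$rep_capacities,
                                     ~ if (length(.x) >= 1) .x[1] else NA_real_),
      rep2_capacity = purrr::map_dbl(.data$rep_capacities,
                                     ~ if (length(.x) >= 2) .x[2] else NA_real_)
    ) %>%
    dplyr::select("plate_id", "sample_id", "dilution", "rank_index",
                  "rep1_capacity", "rep2_capacity", "mean_capacity")
  if (!is.null(path)) readr::write_csv(flat, path, progress = FALSE)
  flat
}
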