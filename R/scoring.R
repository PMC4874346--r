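# Endpoint rank scoring: tri-state classification of per-dilution mean
# capacities and the half-integer 0-8 rank rule.

#' Classify a per-dilution mean capacity as FULL, HALF or NONE
#'
#' Serum either kills the whole inoculum at a dilution or lets it grow to
#' saturation, so mean capacities cluster near 100% and 0%; a 50% mean arises
#' when the two duplicates straddle an individual's threshold dilution. The
#' tri-state call discretises this: `FULL` at or above `full_threshold`,
#' `NONE` at or below `none_threshold`, `HALF` strictly between. The numeric
#' cutoffs are the pipeline's main free parameter; the defaults (95 / 25)
#' reflect that complete killing reads >= 95% while a discordant duplicate
#' pair averages near 50%.
#'
#' @param mean_capacity Percent capacities (vector).
#' @param full_threshold Lower bound for a `FULL` call (default 95).
#' @param none_threshold Upper bound for a `NONE` call (default 25).
#' @return Character vector of calls in `{"FULL","HALF","NONE"}`.
#' @export
classify_dilution <- function(mean_capacity, full_threshold = 95,
                              none_threshold = 25) {
  if (none_threshold >= full_threshold) {
    stop("none_threshold must be below full_threshold", call. = FALSE)
  }
  dplyr::case_when(
    mean_capacity >= full_threshold ~ "FULL",
    mean_capacity <= none_threshold ~ "NONE",
    TRUE ~ "HALF"
  )
}

#' Assign the endpoint rank from an ordered sequence of dilution calls
#'
#' The rank is the highest rank index (dilution step) still called `FULL`.
#' If the call immediately after the last `FULL` is `HALF` — the duplicates
#' straddled the threshold there — the rank is the mean of the two indices
#' (a half-integer). If no dilution reaches `FULL`, the rank is 0, or 0.5
#' when the very first dilution is `HALF` (mean of 0 and 1, the same
#' averaging rule anchored at the rank-0 floor).
#'
#' Non-monotone sequences (a `FULL` reappearing after the first `NONE`) are
#' scored at the last `FULL` before the first `NONE`; the stray later calls
#' trigger a warning and are ignored, as is a `HALF` not adjacent to the
#' last `FULL`.
#'
#' @param calls Character vector of 8 calls (`"FULL"`/`"HALF"`/`"NONE"`),
#'   ordered by rank index 1..8. Shorter series are an error unless
#'   `allow_truncated = TRUE`, in which case missing trailing dilutions are
#'   treated as `NONE` with a warning.
#' @param allow_truncated Accept series shorter than 8?
#' @return A half-integer rank in `{0, 0.5, 1, ..., 8}`.
#' @export
assign_rank <- function(calls, allow_truncated = FALSE) {
  if (length(calls) != 8) {
    if (!allow_truncated || length(calls) > 8) {
      stop("expected calls for all 8 dilutions, got ", length(calls),
           call. = FALSE)
    }
    warning("truncated dilution series: treating missing calls as NONE",
            call. = FALSE)
    calls <- c(calls, rep("NONE", 8 - length(calls)))
  }
  if (!all(calls %in% c("FULL", "HALF", "NONE"))) {
    stop("calls must be FULL, HALF or NONE", call. = FALSE)
  }
  full_idx <- which(calls == "FULL")
  first_none <- if (any(calls == "NONE")) min(which(calls == "NONE")) else 9L
  valid_full <- full_idx[full_idx < first_none]
  if (length(full_idx) > length(valid_full)) {
    warning("non-monotone call sequence: FULL after the first NONE ignored",
            call. = FALSE)
  }
  last_full <- if (length(valid_full) > 0) max(valid_full) else 0L
  rank <- as.numeric(last_full)
  if (last_full < 8 && calls[last_full + 1] == "HALF") {
    rank <- last_full + 0.5
  }
  stray_half <- which(calls == "HALF")
  stray_half <- stray_half[stray_half != last_full + 1]
  if (length(stray_half) > 0) {
    warning("HALF call(s) not adjacent to the last FULL ignored",
            call. = FALSE)
  }
  rank
}

#' Score a capacity table into endpoint ranks
#'
#' Classifies every ranked dilution of every sample and applies the endpoint
#' rank rule, then joins sample metadata. Also produces the deduplicated
#' "one sample per individual" view used for cross-sectional species
#' comparisons, picking one sample per individual uniformly at random under
#' the given seed.
#'
#' @param capacities A `bka_capacity` tibble (from [quantify_plates()]).
#' @param meta Sample metadata (see [read_sample_meta()]).
#' @param full_threshold,none_threshold Classification cutoffs, see
#'   [classify_dilution()].
#' @param dedup_seed Integer seed for the one-sample-per-individual draw.
#' @param allow_truncated Accept samples with fewer than 8 ranked dilutions?
#' @return A list of class `bka_ranks` with elements `ranks` (tibble:
#'   `sample_id`, `individual_id`, `species`, `sex`, `sampling_year`,
#'   `storage_years`, `rank`), `dedup` (same columns, one row per
#'   individual) and `params`.
#' @export
score_dataset <- function(capacities, meta, full_threshold = 95,
                          none_threshold = 25, dedup_seed = 1L,
                          allow_truncated = FALSE) {
  meta <- validate_sample_meta(meta)
  ranked <- capacities[!is.na(capacities$rank_index), ]
  orphans <- setdiff(unique(ranked$sample_id), meta$sample_id)
  if (length(orphans) > 0) {
    stop("sample_id(s) without metadata: ",
         paste(utils::head(orphans, 10), collapse = ", "), call. = FALSE)
  }
  ranks <- ranked %>%
    dplyr::mutate(call = classify_dilution(.data$mean_capacity,
                                           full_threshold, none_threshold)) %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::arrange(.data$rank_index, .by_group = TRUE) %>%
    dplyr::summarise(
      rank = {
        if (!allow_truncated && dplyr::n() != 8) {
          stop("sample ", .data$sample_id[1], " has ", dplyr::n(),
               " ranked dilutions (expected 8)", call. = FALSE)
        }
        assign_rank(.data$call, allow_truncated = allow_truncated)
      },
      .groups = "drop"
    ) %>%
    dplyr::inner_join(meta, by = "sample_id") %>%
    dplyr::select("sample_id", "individual_id", "species", "sex",
                  "sampling_year", "storage_years", "rank") %>%
    dplyr::arrange(.data$species, .data$individual_id, .data$sampling_year)

  dedup <- local({
    old <- .Random.seed_exists()
    set.seed(as.integer(dedup_seed))
    on.exit(restore_seed(old), add = TRUE)
    ranks %>%
      dplyr::group_by(.data$individual_id) %>%
      dplyr::slice_sample(n = 1) %>%
      dplyr::ungroup() %>%
      dplyr::arrange(.data$species, .data$individual_id)
  })

  structure(
    list(ranks = ranks, dedup = dedup,
         params = list(full_threshold = full_threshold,
                       none_threshold = none_threshold,
                       dedup_seed = as.integer(dedup_seed))),
    class = "bka_ranks"
  )
}

#' @export
print.bka_ranks <- function(x, ...) {
  cat("BKA endpoint ranks:", nrow(x$ranks), "samples,",
      nrow(x$dedup), "individuals (deduplicated view)\n")
  cat("thresholds: FULL >=", x$params$full_threshold,
      "| NONE <=", x$params$none_threshold,
      "| dedup seed", x$params$dedup_seed, "\n")
  print(dplyr::count(x$ranks, .data$species,
                     name = "n_samples"), ...)
  invisible(x)
}

# Save/restore the RNG state so seeded sub-draws do not perturb callers.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
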