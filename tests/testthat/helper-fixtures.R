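# In-code fixtures: tiny plates with known arithmetic, plus small
# combinatorial utilities used by the enumeration oracles.

# A plate where every sample well has a prescribed corrected-growth level.
# `growth` is a function(sample_id, dilution, replicate) -> raw growth (AU);
# baseline abs_0h is constant, controls noise-free.
make_plate <- function(sample_ids, dilutions = RANKED_DILUTIONS,
                       growth = function(s, d, r) 0,
                       abs_0h = 0.5, pos_growth = 0.4, neg_drift = 0,
                       n_controls = 2, plate_id = "P1") {
  grid <- expand.grid(sample_id = sample_ids, dilution = dilutions,
                      replicate = 1:2, stringsAsFactors = FALSE)
  g <- unname(mapply(growth, grid$sample_id, grid$dilution, grid$replicate))
  smp <- tibble::tibble(
    plate_id = plate_id, role = "SAMPLE", sample_id = grid$sample_id,
    dilution = grid$dilution, replicate = as.integer(grid$replicate),
    abs_0h = abs_0h, abs_12h = abs_0h + g
  )
  ctl_12h <- c(rep(abs_0h + neg_drift, n_controls),
               rep(abs_0h + pos_growth, n_controls))
  ctl <- tibble::tibble(
    plate_id = plate_id,
    role = rep(c("NEGATIVE_CONTROL", "POSITIVE_CONTROL"), each = n_controls),
    sample_id = NA_character_, dilution = NA_real_,
    replicate = rep(seq_len(n_controls), 2),
    abs_0h = abs_0h,
    abs_12h = ctl_12h
  )
  tbl <- dplyr::bind_rows(smp, ctl)
  tbl$well <- paste0(rep(LETTERS[1:8], length.out = nrow(tbl)),
                     rep(1:12, each = 8, length.out = nrow(tbl)))
  # ensure unique labels even beyond 96 rows
  tbl$well <- paste0(tbl$well, "_", seq_len(nrow(tbl)))
  as_bka_plate(tbl[, c("plate_id", "well", "role", "sample_id", "dilution",
                       "replicate", "abs_0h", "abs_12h")])
}

# Growth function for a threshold-type sample: zero growth (killing) at
# dilution index <= t, saturated growth beyond.
threshold_growth <- function(thresholds, sat = 0.4) {
  function(s, d, r) if (log2(d) <= thresholds[[s]]) 0 else sat
}

# Metadata for a set of samples, one individual each unless stated.
make_meta <- function(sample_ids, species = "cheetah",
                      individual_id = sample_ids, sex = "F",
                      sampling_year = 2010, storage_years = 3.5) {
  tibble::tibble(sample_id = sample_ids, individual_id = individual_id,
                 species = species, sex = sex,
                 sampling_year = sampling_year,
                 storage_years = storage_years)
}

# All permutations of a vector (n <= 8), for enumeration oracles.
all_perms <- function(v) {
  n <- length(v)
  if (n == 1) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

expect_perm_test <- function(x) {
  expect_s3_class(x, "perm_test")
  expect_true(is.finite(x$statistic))
  expect_gte(x$p_value, 0)
  expect_lte(x$p_value, 1)
}
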