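# Nonparametric test engines. Every Monte-Carlo p-value is the add-one
# estimator (b + 1) / (B + 1), where b counts permutations with a statistic
# at least as extreme as observed, so p >= 1/(B + 1) and repeated calls with
# the same seed are bit-identical.

new_perm_test <- function(statistic_name, statistic, p_value, method,
                          n_permutations = NA_integer_, seed = NA_integer_,
                          df = NA_integer_, alternative = NA_character_,
                          extra = list()) {
  structure(
    c(list(statistic_name = statistic_name,
           statistic = as.numeric(statistic),
           df = df,
           p_value = as.numeric(p_value),
           method = method,
           n_permutations = as.integer(n_permutations),
           seed = if (is.na(seed)) NA_integer_ else as.integer(seed),
           alternative = alternative),
      extra),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(x$statistic_name, "=", format(x$statistic, digits = 6))
  if (!is.na(x$df)) cat(", df =", x$df)
  cat(", p =", format(x$p_value, digits = 4))
  cat(" [", x$method, sep = "")
  if (!is.na(x$n_permutations)) cat(", B =", x$n_permutations)
  if (!is.na(x$seed)) cat(", seed =", x$seed)
  cat("]\n")
  invisible(x)
}

#' Tidy a permutation-test result
#'
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @return A one-row tibble with the statistic, degrees of freedom, p-value,
#'   method, permutation count and seed.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    statistic_name = x$statistic_name,
    statistic = x$statistic,
    df = x$df,
    p.value = x$p_value,
    method = x$method,
    n_permutations = x$n_permutations,
    seed = x$seed,
    alternative = x$alternative
  )
}

#' @rdname tidy.perm_test
#' @export
glance.perm_test <- function(x, ...) tidy.perm_test(x, ...)

mc_p <- function(b, B) (b + 1) / (B + 1)

with_seed <- function(seed, expr) {
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  on.exit(restore_seed(old), add = TRUE)
  force(expr)
}

as_group_list <- function(x, g = NULL) {
  if (is.null(g)) {
    if (!is.list(x)) stop("supply a list of groups or (values, groups)",
                          call. = FALSE)
    return(lapply(x, as.numeric))
  }
  split(as.numeric(x), g)
}

# Tie-corrected Kruskal-Wallis H from pooled mid-ranks.
kw_statistic <- function(r, sizes) {
  N <- length(r)
  grp_end <- cumsum(sizes)
  grp_start <- c(1, utils::head(grp_end, -1) + 1)
  Rj <- vapply(seq_along(sizes),
               function(j) sum(r[grp_start[j]:grp_end[j]]), numeric(1))
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / sizes) - 3 * (N + 1)
  tie <- table(r)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (C > 0) H / C else 0
}

#' Kruskal-Wallis test on two or more groups
#'
#' Tie-corrected H statistic; the p-value is asymptotic chi-squared with
#' k - 1 degrees of freedom by default, or a seeded Monte-Carlo permutation
#' p (group labels permuted) for small samples.
#'
#' @param x A list of numeric groups, or a numeric vector when `g` is given.
#' @param g Optional grouping factor aligned with `x`.
#' @param method `"asymptotic"` (default) or `"monte_carlo"`.
#' @param n_perm Number of permutations for the Monte-Carlo route.
#' @param seed Seed for the Monte-Carlo route.
#' @return A `perm_test` with statistic `H`.
#' @export
kruskal_wallis <- function(x, g = NULL,
                           method = c("asymptotic", "monte_carlo"),
                           n_perm = 10000, seed = 1L) {
  method <- match.arg(method)
  groups <- as_group_list(x, g)
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0)) stop("empty group", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  r <- rank(pooled)
  H <- kw_statistic(r, sizes)
  df <- length(groups) - 1L
  if (method == "asymptotic") {
    p <- stats::pchisq(H, df = df, lower.tail = FALSE)
    return(new_perm_test("H", H, p, "ASYMPTOTIC", df = df,
                         alternative = "two.sided"))
  }
  b <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      kw_statistic(sample(r), sizes) >= H
    }, logical(1)))
  })
  new_perm_test("H", H, mc_p(b, n_perm), "MONTE_CARLO", n_perm, seed,
                df = df, alternative = "two.sided")
}

# Standardized pairwise Wilcoxon statistic with mid-rank tie correction,
# scaled by sqrt(2) as in the Dwass-Steel-Critchlow-Fligner procedure.
dscf_pair_statistic <- function(xi, xj) {
  ni <- length(xi); nj <- length(xj)
  r <- rank(c(xi, xj))
  W <- sum(r[seq_len(ni)])
  mu <- ni * (ni + nj + 1) / 2
  N <- ni + nj
  tie <- table(r)
  sigma2 <- ni * nj / 12 * (N + 1 - sum(tie^3 - tie) / (N * (N - 1)))
  if (sigma2 <= 0) return(0)
  sqrt(2) * (W - mu) / sqrt(sigma2)
}

#' Dwass-Steel-Critchlow-Fligner all-pairs posthoc comparisons
#'
#' For each pair of groups, the standardized pairwise Wilcoxon statistic
#' (mid-rank tie correction, Studentized-range scaling) is referenced
#' against its seeded Monte-Carlo permutation null: the pooled pair is
#' repeatedly re-split at the observed group sizes and the absolute
#' standardized statistic recomputed.
#'
#' @param x A list of >= 3 numeric groups (named for labelled output), or a
#'   numeric vector with grouping factor `g`.
#' @param g Optional grouping factor.
#' @param n_perm Permutations per pair (default 1000).
#' @param seed Seed; each pair derives its own stream deterministically.
#' @return A list of class `dscf_posthoc`: `pairs` (tibble with group1,
#'   group2, statistic, p.value, n_permutations), `p_matrix` (symmetric,
#'   diagonal 1), `n_permutations`, `seed`.
#' @export
dscf_posthoc <- function(x, g = NULL, n_perm = 1000, seed = 1L) {
  groups <- as_group_list(x, g)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  if (length(groups) < 3) stop("DSCF posthoc needs >= 3 groups", call. = FALSE)
  k <- length(groups)
  labs <- names(groups)
  pm <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  diag(pm) <- 1
  rows <- list()
  pair_id <- 0L
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      pair_id <- pair_id + 1L
      xi <- groups[[i]]; xj <- groups[[j]]
      if (length(xi) < 2 || length(xj) < 2) {
        warning("pair (", labs[i], ", ", labs[j],
                ") skipped: group of size < 2", call. = FALSE)
        next
      }
      obs <- abs(dscf_pair_statistic(xi, xj))
      pooled <- c(xi, xj)
      ni <- length(xi)
      b <- with_seed(seed + pair_id, {
        sum(vapply(seq_len(n_perm), function(s) {
          idx <- sample.int(length(pooled), ni)
          abs(dscf_pair_statistic(pooled[idx], pooled[-idx])) >= obs
        }, logical(1)))
      })
      p <- mc_p(b, n_perm)
      pm[i, j] <- pm[j, i] <- p
      rows[[pair_id]] <- tibble::tibble(
        group1 = labs[i], group2 = labs[j],
        statistic = dscf_pair_statistic(xi, xj),
        p.value = p, n_permutations = as.integer(n_perm)
      )
    }
  }
  structure(
    list(pairs = dplyr::bind_rows(rows), p_matrix = pm,
         n_permutations = as.integer(n_perm), seed = as.integer(seed)),
    class = "dscf_posthoc"
  )
}

#' @export
print.dscf_posthoc <- function(x, ...) {
  cat("DSCF all-pairs posthoc (Monte Carlo, B =", x$n_permutations,
      ", seed =", x$seed, ")\n")
  print(round(x$p_matrix, 4), ...)
  invisible(x)
}

#' @rdname tidy.perm_test
#' @export
tidy.dscf_posthoc <- function(x, ...) x$pairs

# JT = sum over ordered group pairs (i < j) of Mann-Whitney counts of
# pairs (a in group i, b in group j) with a < b, ties counted 1/2.
jt_statistic <- function(values, grp_end) {
  k <- length(grp_end)
  grp_start <- c(1, utils::head(grp_end, -1) + 1)
  jt <- 0
  for (i in seq_len(k - 1)) {
    xi <- values[grp_start[i]:grp_end[i]]
    for (j in seq(i + 1, k)) {
      xj <- values[grp_start[j]:grp_end[j]]
      cmp <- outer(xi, xj, "<") + 0.5 * outer(xi, xj, "==")
      jt <- jt + sum(cmp)
    }
  }
  jt
}

#' Jonckheere-Terpstra test for a monotone trend across ordered groups
#'
#' The statistic is the sum of pairwise Mann-Whitney counts over all ordered
#' group pairs (ties contribute 1/2). The permutation p-value shuffles
#' observations across groups keeping group sizes; the two-sided p doubles
#' the smaller tail and is capped at 1.
#'
#' @param x A list of numeric groups in their declared order (e.g. by
#'   storage years), or values with ordered grouping factor `g`.
#' @param g Optional grouping factor; its level order defines the trend
#'   ordering (a plain factor's levels must therefore already be ordered).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Seed.
#' @param alternative `"two.sided"` (default), `"increasing"` or
#'   `"decreasing"`.
#' @return A `perm_test` with statistic `JT`.
#' @export
jonckheere_terpstra <- function(x, g = NULL, n_perm = 10000, seed = 1L,
                                alternative = c("two.sided", "increasing",
                                                "decreasing")) {
  alternative <- match.arg(alternative)
  groups <- as_group_list(x, g)
  if (length(groups) < 2) stop("need >= 2 ordered groups", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  grp_end <- cumsum(lengths(groups))
  JT <- jt_statistic(values, grp_end)
  counts <- with_seed(seed, {
    up <- 0L; dn <- 0L
    for (s in seq_len(n_perm)) {
      jt_s <- jt_statistic(sample(values), grp_end)
      if (jt_s >= JT) up <- up + 1L
      if (jt_s <= JT) dn <- dn + 1L
    }
    c(up = up, dn = dn)
  })
  p_up <- mc_p(counts["up"], n_perm)
  p_dn <- mc_p(counts["dn"], n_perm)
  p <- switch(alternative,
    two.sided = min(1, 2 * min(p_up, p_dn)),
    increasing = p_up,
    decreasing = p_dn
  )
  new_perm_test("JT", JT, unname(p), "MONTE_CARLO", n_perm, seed,
                alternative = alternative)
}

# Skillings-Mack machinery. `mat` is blocks x treatments with NA for
# unobserved cells. Returns the weighted centered-rank vector A and the
# design covariance Sigma.
sm_components <- function(mat) {
  k <- ncol(mat)
  A <- numeric(k)
  Sigma <- matrix(0, k, k)
  for (b in seq_len(nrow(mat))) {
    obs <- which(!is.na(mat[b, ]))
    s <- length(obs)
    if (s < 2) next
    r <- rank(mat[b, obs])
    w <- sqrt(12 / (s + 1))
    A[obs] <- A[obs] + w * (r - (s + 1) / 2)
    for (ii in obs) for (jj in obs) {
      if (ii == jj) Sigma[ii, ii] <- Sigma[ii, ii] + (s - 1)
      else Sigma[ii, jj] <- Sigma[ii, jj] - 1
    }
  }
  list(A = A, Sigma = Sigma)
}

sm_statistic_from_A <- function(A, Sigma_ginv) {
  as.numeric(t(A) %*% Sigma_ginv %*% A)
}

#' Skillings-Mack test for incomplete block designs
#'
#' Generalizes the Friedman test to blocks that miss treatment levels:
#' observations are ranked within blocks, centered, weighted by
#' `sqrt(12 / (s + 1))` for a block observing `s` levels, and the quadratic
#' form in the generalized inverse of the design covariance is the
#' statistic. On complete balanced blocks it reduces exactly to Friedman's
#' statistic. The p-value permutes observations within blocks.
#'
#' @param y Observations.
#' @param blocks Block identifiers (e.g. individual), aligned with `y`.
#' @param treatments Treatment levels (e.g. sampling occasion), aligned.
#' @param n_perm Number of within-block permutations (default 10000).
#' @param seed Seed.
#' @return A `perm_test` with statistic `SM` and `df = k - 1`. Blocks with
#'   fewer than 2 observed levels are dropped with a warning.
#' @export
skillings_mack <- function(y, blocks, treatments, n_perm = 10000, seed = 1L) {
  blocks <- as.character(blocks)
  tr_lev <- sort(unique(as.character(treatments)))
  bl_lev <- unique(blocks)
  if (length(tr_lev) < 2) stop("need >= 2 treatment levels", call. = FALSE)
  mat <- matrix(NA_real_, length(bl_lev), length(tr_lev),
                dimnames = list(bl_lev, tr_lev))
  mat[cbind(match(blocks, bl_lev), match(as.character(treatments), tr_lev))] <- y
  keep <- rowSums(!is.na(mat)) >= 2
  if (any(!keep)) {
    warning(sum(!keep), " block(s) with < 2 observed levels excluded",
            call. = FALSE)
    mat <- mat[keep, , drop = FALSE]
  }
  if (nrow(mat) < 2) stop("need >= 2 usable blocks", call. = FALSE)
  comp <- sm_components(mat)
  Sg <- MASS::ginv(comp$Sigma)
  SM <- sm_statistic_from_A(comp$A, Sg)
  obs_idx <- lapply(seq_len(nrow(mat)), function(b) which(!is.na(mat[b, ])))
  b_ge <- with_seed(seed, {
    n_ge <- 0L
    for (s in seq_len(n_perm)) {
      pm <- mat
      for (b in seq_len(nrow(mat))) {
        ob <- obs_idx[[b]]
        pm[b, ob] <- mat[b, ob][sample.int(length(ob))]
      }
      A_s <- sm_components(pm)$A
      if (sm_statistic_from_A(A_s, Sg) >= SM) n_ge <- n_ge + 1L
    }
    n_ge
  })
  new_perm_test("SM", SM, mc_p(b_ge, n_perm), "MONTE_CARLO", n_perm, seed,
                df = length(tr_lev) - 1L, alternative = "two.sided")
}

#' Fisher's exact test on an r x c contingency table
#'
#' Two-sided p-value as the probability mass, under the fixed-margin
#' hypergeometric null, of tables no more probable than the observed one —
#' by network/enumeration for small tables or seeded Monte-Carlo sampling
#' for large ones.
#'
#' @param table An r x c matrix of non-negative integer counts; all row and
#'   column margins must be positive.
#' @param method `"enumeration"` (network algorithm, default) or
#'   `"monte_carlo"`.
#' @param n_draws Monte-Carlo table draws (default 10000).
#' @param seed Seed for the Monte-Carlo route.
#' @return A `perm_test`; the statistic is the observed table's
#'   hypergeometric log-probability.
#' @export
fisher_exact_rxc <- function(table, method = c("enumeration", "monte_carlo"),
                             n_draws = 10000, seed = 1L) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("table must hold non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all table margins must be positive", call. = FALSE)
  }
  logp_obs <- sum(lgamma(rowSums(table) + 1)) + sum(lgamma(colSums(table) + 1)) -
    lgamma(sum(table) + 1) - sum(lgamma(table + 1))
  if (method == "enumeration") {
    ft <- stats::fisher.test(table, workspace = 2e7)
    return(new_perm_test("log P(table)", logp_obs, ft$p.value,
                         "EXACT_ENUMERATION", alternative = "two.sided"))
  }
  ft <- with_seed(seed,
    stats::fisher.test(table, simulate.p.value = TRUE, B = n_draws))
  new_perm_test("log P(table)", logp_obs, ft$p.value, "MONTE_CARLO",
                n_draws, seed, alternative = "two.sided")
}

#' Mantel test between two labelled distance matrices
#'
#' Pearson correlation of the lower-triangle entries after aligning the two
#' matrices by label (never by position); the permutation null relabels one
#' matrix's rows and columns jointly. One-sided (positive association) by
#' default, matching the usual phylogenetic-signal question.
#'
#' @param D1,D2 Symmetric zero-diagonal matrices with identical label sets
#'   (dimnames), or `dist` objects with labels, or labelled square data
#'   frames.
#' @param n_perm Number of label permutations (default 9999).
#' @param seed Seed.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return A `perm_test` with statistic `r`.
#' @export
mantel_test <- function(D1, D2, n_perm = 9999, seed = 1L,
                        alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  D1 <- as_distance_matrix(D1)
  D2 <- as_distance_matrix(D2)
  labs <- rownames(D1)
  if (!setequal(labs, rownames(D2))) {
    stop("label mismatch between matrices: ",
         paste(union(setdiff(labs, rownames(D2)),
                     setdiff(rownames(D2), labs)), collapse = ", "),
         call. = FALSE)
  }
  D2 <- D2[labs, labs]
  lt <- lower.tri(D1)
  v1 <- D1[lt]
  r_obs <- stats::cor(v1, D2[lt])
  n <- length(labs)
  counts <- with_seed(seed, {
    ge <- 0L; le <- 0L
    for (s in seq_len(n_perm)) {
      pidx <- sample.int(n)
      r_s <- stats::cor(v1, D2[pidx, pidx][lt])
      if (r_s >= r_obs) ge <- ge + 1L
      if (r_s <= r_obs) le <- le + 1L
    }
    c(ge = ge, le = le)
  })
  p <- switch(alternative,
    greater = mc_p(counts["ge"], n_perm),
    less = mc_p(counts["le"], n_perm),
    two.sided = min(1, 2 * min(mc_p(counts["ge"], n_perm),
                               mc_p(counts["le"], n_perm)))
  )
  new_perm_test("r", r_obs, unname(p), "MONTE_CARLO", n_perm, seed,
                alternative = alternative)
}
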