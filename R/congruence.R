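# Species-level profile aggregation, distance matrices, centroid-linkage
# clustering and tree comparison against an external phylogeny.

#' Coerce to a validated labelled distance matrix
#'
#' @param x A labelled square matrix, data frame (first column or row names
#'   as labels), or `dist` object.
#' @param tol Symmetry tolerance.
#' @return A symmetric numeric matrix with zero diagonal and dimnames.
#' @export
as_distance_matrix <- function(x, tol = 1e-8) {
  if (inherits(x, "dist")) x <- as.matrix(x)
  if (is.data.frame(x)) {
    if (!is.numeric(x[[1]])) {
      labs <- as.character(x[[1]])
      x <- as.matrix(x[, -1, drop = FALSE])
      rownames(x) <- labs
    } else {
      x <- as.matrix(x)
    }
  }
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(x)) && is.null(colnames(x))) {
    stop("distance matrix must carry labels", call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- colnames(x)
  if (is.null(colnames(x))) colnames(x) <- rownames(x)
  if (!isTRUE(all.equal(rownames(x), colnames(x)))) {
    x <- x[, rownames(x), drop = FALSE]
  }
  if (max(abs(x - t(x))) > tol) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (max(abs(diag(x))) > tol) {
    stop("distance matrix diagonal must be zero", call. = FALSE)
  }
  x <- (x + t(x)) / 2
  diag(x) <- 0
  x
}

#' Read a labelled distance matrix, or patristic distances from Newick
#'
#' @param path A CSV with labels in the first column and matching column
#'   headers, or a Newick tree file (`.nwk`/`.tre`/`.tree`/`.newick`), from
#'   which cophenetic (patristic) distances are computed.
#' @return A labelled symmetric matrix.
#' @export
read_distance_matrix <- function(path) {
  if (grepl("\\.(nwk|tre|tree|newick)$", path, ignore.case = TRUE)) {
    tr <- ape::read.tree(path)
    return(as_distance_matrix(stats::cophenetic(tr)))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_distance_matrix(df)
}

#' Per-species mean killing-capacity profiles over the 8 ranked dilutions
#'
#' Averages each species' per-sample mean capacities at each ranked
#' dilution. The deduplication policy (one sample per individual) should be
#' applied upstream; pass the sample ids to keep via `sample_ids`.
#'
#' @param capacities A `bka_capacity` tibble.
#' @param meta Sample metadata.
#' @param sample_ids Optional sample ids to restrict to (e.g. the
#'   deduplicated view from [score_dataset()]).
#' @return A tibble of class `bka_profiles`: one row per
#'   species x rank_index with `mean_capacity` and `n_samples`.
#' @export
species_mean_profiles <- function(capacities, meta, sample_ids = NULL) {
  meta <- validate_sample_meta(meta)
  ranked <- capacities[!is.na(capacities$rank_index), ]
  if (!is.null(sample_ids)) {
    ranked <- ranked[ranked$sample_id %in% sample_ids, ]
  }
  orphans <- setdiff(unique(ranked$sample_id), meta$sample_id)
  if (length(orphans) > 0) {
    stop("sample_id(s) without species metadata: ",
         paste(utils::head(orphans, 10), collapse = ", "), call. = FALSE)
  }
  prof <- ranked %>%
    dplyr::inner_join(meta[, c("sample_id", "species")], by = "sample_id") %>%
    dplyr::group_by(.data$species, .data$rank_index) %>%
    dplyr::summarise(mean_capacity = mean(.data$mean_capacity),
                     n_samples = dplyr::n_distinct(.data$sample_id),
                     .groups = "drop") %>%
    dplyr::arrange(.data$species, .data$rank_index)
  absent <- setdiff(unique(meta$species), prof$species)
  if (length(absent) > 0) {
    warning("species with zero samples excluded: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  bad <- prof %>% dplyr::count(.data$species) %>% dplyr::filter(.data$n != 8)
  if (nrow(bad) > 0) {
    stop("species without all 8 ranked dilutions: ",
         paste(bad$species, collapse = ", "), call. = FALSE)
  }
  class(prof) <- c("bka_profiles", class(tibble::tibble()))
  prof
}

profiles_to_matrix <- function(profiles) {
  wide <- profiles %>%
    tidyr::pivot_wider(id_cols = "species", names_from = "rank_index",
                       values_from = "mean_capacity", names_prefix = "d")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$species
  m[, paste0("d", 1:8), drop = FALSE]
}

#' Euclidean distance matrix between species profiles
#'
#' @param profiles A `bka_profiles` tibble (or a labelled numeric matrix,
#'   species in rows).
#' @return A labelled symmetric distance matrix.
#' @export
euclidean_distance_matrix <- function(profiles) {
  m <- if (is.matrix(profiles)) profiles else profiles_to_matrix(profiles)
  if (nrow(m) < 2) stop("need >= 2 profiles", call. = FALSE)
  if (anyNA(m)) stop("profiles have unequal/missing dilution coverage",
                     call. = FALSE)
  as_distance_matrix(as.matrix(stats::dist(m, method = "euclidean")))
}

#' Centroid-linkage hierarchical clustering of species profiles
#'
#' Agglomerative clustering with centroid (UPGMC) linkage on the Euclidean
#' geometry of the profile vectors. Centroid linkage is computed on squared
#' Euclidean distances (the geometry in which centroids live); merge heights
#' are reported back on the Euclidean scale. Labels are sorted
#' lexicographically before clustering so that among tied merge candidates
#' the lexicographically smallest label pair merges first; the result is
#' therefore invariant to input row order. Centroid linkage can produce
#' height inversions (a merge lower than an earlier one); these are recorded
#' in the result, not hidden.
#'
#' @param profiles A `bka_profiles` tibble or labelled numeric matrix.
#' @return An object of class `bka_tree` wrapping the `hclust` merge
#'   structure with Euclidean-scale `height`, `labels`, and `inversions`
#'   (indices of merges lower than their predecessor).
#' @export
centroid_cluster <- function(profiles) {
  m <- if (is.matrix(profiles)) profiles else profiles_to_matrix(profiles)
  if (nrow(m) < 2) stop("need >= 2 profiles", call. = FALSE)
  m <- m[order(rownames(m)), , drop = FALSE]
  d2 <- stats::dist(m, method = "euclidean")^2
  hc <- stats::hclust(d2, method = "centroid")
  hc$height <- sqrt(pmax(hc$height, 0))
  inv <- which(diff(hc$height) < 0) + 1L
  structure(list(hclust = hc, labels = hc$labels, inversions = inv),
            class = "bka_tree")
}

#' @export
print.bka_tree <- function(x, ...) {
  cat("Centroid-linkage cluster tree,", length(x$labels), "leaves\n")
  cat("merge heights:", paste(round(x$hclust$height, 3), collapse = ", "),
      "\n")
  if (length(x$inversions) > 0) {
    cat("height inversions at merge step(s):",
        paste(x$inversions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a cluster tree as Newick
#'
#' Heights are split at the midpoint: a pair merging at height h gets two
#' branches of length h/2 (the ultrametric reading of the dendrogram).
#' Inverted (negative-length) internal branches, possible under centroid
#' linkage, are preserved as-is.
#'
#' @param tree A `bka_tree` (or `hclust`).
#' @param path Optional file to write.
#' @return The Newick string, invisibly written to `path` if given.
#' @export
tree_to_newick <- function(tree, path = NULL) {
  hc <- if (inherits(tree, "bka_tree")) tree$hclust else tree
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) writeLines(txt, path)
  txt
}

#' Robinson-Foulds topology distance between two trees
#'
#' Counts the bipartitions present in exactly one of the two unrooted
#' topologies (branch lengths ignored).
#'
#' @param t1,t2 `bka_tree`, `phylo`, or Newick strings/file paths; leaf
#'   sets must match.
#' @return A non-negative integer.
#' @export
topology_distance <- function(t1, t2) {
  p1 <- as_phylo_tree(t1)
  p2 <- as_phylo_tree(t2)
  if (!setequal(p1$tip.label, p2$tip.label)) {
    stop("leaf-set mismatch: ",
         paste(union(setdiff(p1$tip.label, p2$tip.label),
                     setdiff(p2$tip.label, p1$tip.label)), collapse = ", "),
         call. = FALSE)
  }
  as.integer(round(ape::dist.topo(ape::unroot(p1), ape::unroot(p2),
                                  method = "PH85")))
}

as_phylo_tree <- function(x) {
  if (inherits(x, "bka_tree")) return(ape::as.phylo(x$hclust))
  if (inherits(x, "hclust")) return(ape::as.phylo(x))
  if (inherits(x, "phylo")) return(x)
  if (is.character(x) && length(x) == 1) {
    if (file.exists(x)) return(ape::read.tree(x))
    return(ape::read.tree(text = x))
  }
  stop("cannot interpret tree input", call. = FALSE)
}

#' Write a labelled distance matrix as CSV
#'
#' @param D A labelled symmetric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  D <- as_distance_matrix(D)
  df <- tibble::as_tibble(D, rownames = "species")
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
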