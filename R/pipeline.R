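# End-to-end orchestration: plates -> quantify -> scoring -> stats ->
# congruence, with explicit seeds and a machine-readable provenance record.

#' Default pipeline configuration
#'
#' @param plates_path,meta_path,phylo_path Input file paths (plate CSV,
#'   metadata CSV, phylogenetic distances CSV/Newick). `phylo_path` may be
#'   `NULL`: the congruence stage against the phylogeny is then skipped and
#'   recorded as skipped.
#' @param sign_convention,positive_mode,clip Quantification settings, see
#'   [quantify_plate()].
#' @param full_threshold,none_threshold Classification cutoffs.
#' @param dedup_seed Seed for the one-sample-per-individual draw.
#' @param mantel_perm,mantel_seed Mantel permutation count and seed.
#' @param dscf_perm,dscf_seed DSCF permutation count and seed.
#' @param out_dir Optional output directory for the result bundle.
#' @return A named list (class `bka_config`).
#' @export
pipeline_config <- function(plates_path = NULL, meta_path = NULL,
                            phylo_path = NULL,
                            sign_convention = "add",
                            positive_mode = "corrected", clip = FALSE,
                            full_threshold = 95, none_threshold = 25,
                            dedup_seed = 1L,
                            mantel_perm = 9999L, mantel_seed = 1L,
                            dscf_perm = 1000L, dscf_seed = 1L,
                            out_dir = NULL) {
  structure(list(
    plates_path = plates_path, meta_path = meta_path,
    phylo_path = phylo_path,
    sign_convention = sign_convention, positive_mode = positive_mode,
    clip = clip, full_threshold = full_threshold,
    none_threshold = none_threshold, dedup_seed = as.integer(dedup_seed),
    mantel_perm = as.integer(mantel_perm),
    mantel_seed = as.integer(mantel_seed),
    dscf_perm = as.integer(dscf_perm), dscf_seed = as.integer(dscf_seed),
    out_dir = out_dir
  ), class = "bka_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `bka_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes plate reading (or takes in-memory inputs), quantification,
#' rank scoring, the species-level hypothesis tests (Kruskal-Wallis with
#' DSCF posthoc), and the congruence stage (species mean profiles,
#' Euclidean distance matrix, centroid clustering, and — when a phylogeny
#' is supplied — the Mantel test and topology distance). Every stochastic
#' step runs under a seed recorded in the provenance entry of the result.
#'
#' @param config A `bka_config` from [pipeline_config()] or a path to a
#'   YAML config.
#' @param plates,meta,phylo Optional in-memory inputs overriding the
#'   configured paths.
#' @return A list of class `bka_result` with elements `capacities`,
#'   `ranks` (a `bka_ranks`), `profiles`, `bka_distances`, `tree`,
#'   `newick`, `kw`, `dscf`, `mantel`, `topo_distance`, `skipped`, and
#'   `provenance`. If `config$out_dir` is set, CSV/JSON/Newick artifacts
#'   are written there.
#' @export
run_pipeline <- function(config = pipeline_config(), plates = NULL,
                         meta = NULL, phylo = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(plates)) {
    if (is.null(config$plates_path)) stop("no plate input", call. = FALSE)
    plates <- read_plate_table(config$plates_path)
  }
  plates <- as_bka_plate(plates)
  if (is.null(meta)) {
    if (is.null(config$meta_path)) stop("no metadata input", call. = FALSE)
    meta <- read_sample_meta(config$meta_path)
  }
  meta <- validate_sample_meta(meta)
  if (is.null(phylo) && !is.null(config$phylo_path)) {
    phylo <- read_distance_matrix(config$phylo_path)
  }

  capacities <- quantify_plates(plates,
                                sign_convention = config$sign_convention,
                                positive_mode = config$positive_mode,
                                clip = config$clip)
  ranks <- score_dataset(capacities, meta,
                         full_threshold = config$full_threshold,
                         none_threshold = config$none_threshold,
                         dedup_seed = config$dedup_seed)
  dedup <- ranks$dedup
  groups <- split(dedup$rank, dedup$species)
  kw <- kruskal_wallis(groups)
  dscf <- dscf_posthoc(groups, n_perm = config$dscf_perm,
                       seed = config$dscf_seed)
  profiles <- species_mean_profiles(capacities, meta,
                                    sample_ids = dedup$sample_id)
  bka_D <- euclidean_distance_matrix(profiles)
  tree <- centroid_cluster(profiles)
  newick <- tree_to_newick(tree)

  skipped <- character(0)
  mantel <- NULL
  topo <- NULL
  if (is.null(phylo)) {
    skipped <- c(skipped, "mantel", "topology_distance")
  } else {
    phylo <- as_distance_matrix(phylo)
    mantel <- mantel_test(bka_D, phylo, n_perm = config$mantel_perm,
                          seed = config$mantel_seed)
    phylo_tree <- ape::as.phylo(stats::hclust(stats::as.dist(phylo),
                                              method = "average"))
    topo <- topology_distance(tree, phylo_tree)
  }

  provenance <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("bkassay")),
    seeds = list(dedup = config$dedup_seed, mantel = config$mantel_seed,
                 dscf = config$dscf_seed),
    settings = config[c("sign_convention", "positive_mode", "clip",
                        "full_threshold", "none_threshold")],
    n_plates = length(unique(plates$plate_id)),
    n_samples = nrow(ranks$ranks),
    n_individuals = nrow(dedup),
    skipped = skipped
  )

  res <- structure(
    list(capacities = capacities, ranks = ranks, profiles = profiles,
         bka_distances = bka_D, tree = tree, newick = newick,
         kw = kw, dscf = dscf, mantel = mantel, topo_distance = topo,
         skipped = skipped, provenance = provenance),
    class = "bka_result"
  )
  if (!is.null(config$out_dir)) write_result_bundle(res, config$out_dir)
  res
}

write_result_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  capacity_table(res$capacities, file.path(out_dir, "capacities.csv"))
  readr::write_csv(res$ranks$ranks, file.path(out_dir, "ranks.csv"),
                   progress = FALSE)
  readr::write_csv(res$ranks$dedup, file.path(out_dir, "ranks_dedup.csv"),
                   progress = FALSE)
  readr::write_csv(res$profiles, file.path(out_dir, "species_profiles.csv"),
                   progress = FALSE)
  write_distance_matrix(res$bka_distances,
                        file.path(out_dir, "bka_distances.csv"))
  writeLines(res$newick, file.path(out_dir, "bka_tree.nwk"))
  tests <- list(kruskal_wallis = unclass(tidy(res$kw)),
                dscf = unclass(res$dscf$pairs))
  if (!is.null(res$mantel)) {
    tests$mantel <- unclass(tidy(res$mantel))
    tests$topology_distance <- res$topo_distance
  }
  jsonlite::write_json(tests, file.path(out_dir, "test_results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(res$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.bka_result <- function(x, ...) {
  cat("BKA pipeline result —", x$provenance$n_samples, "samples,",
      x$provenance$n_individuals, "individuals,",
      x$provenance$n_plates, "plates\n")
  print(x$kw)
  if (!is.null(x$mantel)) {
    print(x$mantel)
    cat("topology distance to supplied phylogeny:", x$topo_distance, "\n")
  }
  if (length(x$skipped) > 0) {
    cat("skipped stages:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Study-scale summary statistics from a scored ranks table
#'
#' Computes the cross-species Kruskal-Wallis test, the storage-time
#' Jonckheere-Terpstra test for a chosen species, the repeated-measures
#' Skillings-Mack test over sampling occasions, and — when a phylogeny is
#' supplied — the Mantel correlation between the species profile distances
#' and the phylogenetic distances. Intended for externally supplied rank
#' datasets (e.g. a published supplementary table) as well as for pipeline
#' output.
#'
#' @param ranks Tibble with `sample_id`, `individual_id`, `species`,
#'   `sampling_year`, `storage_years`, `rank` (one row per sample).
#' @param profiles Optional `bka_profiles` for the Mantel stage.
#' @param phylo Optional phylogenetic distance matrix (labels = species).
#' @param jt_species Species for the storage-time trend test (default the
#'   most-sampled species).
#' @param dedup_seed,n_perm,seed Seeds and permutation count.
#' @return A list with `kw`, `jt`, `sm`, and (optionally) `mantel`
#'   `perm_test` objects.
#' @export
study_scale_statistics <- function(ranks, profiles = NULL, phylo = NULL,
                                   jt_species = NULL, dedup_seed = 1L,
                                   n_perm = 10000, seed = 1L) {
  ranks <- tibble::as_tibble(ranks)
  dedup <- local({
    old <- .Random.seed_exists()
    set.seed(as.integer(dedup_seed))
    on.exit(restore_seed(old), add = TRUE)
    ranks %>% dplyr::group_by(.data$individual_id) %>%
      dplyr::slice_sample(n = 1) %>% dplyr::ungroup()
  })
  kw <- kruskal_wallis(split(dedup$rank, dedup$species))
  if (is.null(jt_species)) {
    jt_species <- names(sort(table(ranks$species), decreasing = TRUE))[1]
  }
  sp <- ranks[ranks$species == jt_species, ]
  jt_groups <- split(sp$rank, sp$storage_years)
  jt <- jonckheere_terpstra(jt_groups, n_perm = n_perm, seed = seed)
  rep_ids <- names(which(table(ranks$individual_id) >= 2))
  rep_tbl <- ranks[ranks$individual_id %in% rep_ids, ] %>%
    dplyr::group_by(.data$individual_id) %>%
    dplyr::arrange(.data$sampling_year, .by_group = TRUE) %>%
    dplyr::mutate(occasion = dplyr::row_number()) %>%
    dplyr::ungroup()
  sm <- skillings_mack(rep_tbl$rank, rep_tbl$individual_id,
                       rep_tbl$occasion, n_perm = n_perm, seed = seed)
  out <- list(kw = kw, jt = jt, sm = sm)
  if (!is.null(profiles) && !is.null(phylo)) {
    out$mantel <- mantel_test(euclidean_distance_matrix(profiles),
                              as_distance_matrix(phylo),
                              n_perm = n_perm, seed = seed)
  }
  out
}
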