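profiles_fixture <- function(caps) {
  # caps: named list species -> capacity vector of length 8
  dplyr::bind_rows(lapply(names(caps), function(sp) {
    tibble::tibble(species = sp, rank_index = 1:8,
                   mean_capacity = caps[[sp]], n_samples = 1L)
  }))
}

test_that("species_mean_profiles averages per dilution", {
  thr <- list(a1 = 3, a2 = 3, b1 = 6)
  p <- make_plate(names(thr), growth = threshold_growth(thr))
  q <- quantify_plate(p)
  meta <- make_meta(names(thr), species = c("sp_a", "sp_a", "sp_b"))
  prof <- species_mean_profiles(q, meta)
  expect_equal(nrow(prof), 16)
  a <- prof$mean_capacity[prof$species == "sp_a"]
  expect_equal(a, ifelse(1:8 <= 3, 100, 0))
  # one sample per species: profile equals that sample's capacities
  b <- prof$mean_capacity[prof$species == "sp_b"]
  expect_equal(b, ifelse(1:8 <= 6, 100, 0))
  # two samples at 100 and 0 average to the midpoint
  thr2 <- list(c1 = 8, c2 = 0)
  q2 <- quantify_plate(make_plate(names(thr2), growth = threshold_growth(thr2)))
  prof2 <- species_mean_profiles(q2, make_meta(names(thr2), species = "sp_c"))
  expect_equal(prof2$mean_capacity, rep(50, 8))
  # restriction to a sample subset
  prof3 <- species_mean_profiles(q2, make_meta(names(thr2), species = "sp_c"),
                                 sample_ids = "c1")
  expect_equal(prof3$mean_capacity, rep(100, 8))
})

test_that("euclidean_distance_matrix matches a brute-force double loop", {
  set.seed(31)
  m <- matrix(runif(3 * 8, 0, 100), nrow = 3,
              dimnames = list(c("x", "y", "z"), NULL))
  D <- euclidean_distance_matrix(m)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(D[i, j], sqrt(sum((m[i, ] - m[j, ])^2)), tolerance = 1e-12)
  }
  # identical profiles at distance zero; single-axis difference of 10 -> 10
  caps <- list(u = rep(100, 8), v = rep(100, 8),
               w = c(rep(100, 7), 90))
  D2 <- euclidean_distance_matrix(profiles_fixture(caps))
  expect_equal(D2["u", "v"], 0)
  expect_equal(D2["u", "w"], 10)
})

test_that("distance matrices satisfy metric properties on random input", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    m <- matrix(runif(n * 8, 0, 100), nrow = n,
                dimnames = list(paste0("s", seq_len(n)), NULL))
    D <- euclidean_distance_matrix(m)
    expect_equal(D, t(D))
    expect_equal(diag(D), setNames(rep(0, n), rownames(m)))
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-9)
    }
  }
})

test_that("centroid_cluster merges by centroid geometry", {
  # two profiles: a single merge at their Euclidean distance
  caps <- list(a = rep(100, 8), b = rep(90, 8))
  tr <- centroid_cluster(profiles_fixture(caps))
  expect_equal(tr$hclust$height, sqrt(8 * 100))
  expect_equal(sort(tr$labels), c("a", "b"))
  # coincident pair merges first at height 0
  caps3 <- list(far = rep(0, 8), p1 = rep(100, 8), p2 = rep(100, 8))
  tr3 <- centroid_cluster(profiles_fixture(caps3))
  expect_equal(tr3$hclust$height[1], 0)
  first <- tr3$hclust$merge[1, ]
  expect_setequal(tr3$labels[-first], c("p1", "p2"))
  # invariant to input order (labels sorted internally)
  tr3b <- centroid_cluster(profiles_fixture(caps3[c(3, 1, 2)]))
  expect_equal(tree_to_newick(tr3), tree_to_newick(tr3b))
  expect_error(centroid_cluster(profiles_fixture(caps3["far"])), ">= 2")
})

test_that("planted cluster structure is recovered from simulated species", {
  params <- tibble::tibble(
    species = c("hi1", "hi2", "mid1", "mid2", "mid3", "zero"),
    n_individuals = 25L,
    threshold_mean = c(7, 7.2, 4, 4.1, 3.9, 0),
    threshold_sd = c(0.4, 0.4, 0.4, 0.4, 0.4, 0),
    p_discordant = 0.1,
    p_male = 0.5, p_female = 0.5,
    repeats = list(integer(0), integer(0), integer(0), integer(0),
                   integer(0), integer(0))
  )
  sim <- simulate_study(params, seed = 99)
  res <- suppressWarnings(
    run_pipeline(pipeline_config(), plates = sim$plates, meta = sim$meta))
  hc <- res$tree$hclust
  # the two high-threshold species are each other's first merge partner
  pair_steps <- which(apply(hc$merge, 1, function(r) all(r < 0)))
  leaf_pairs <- lapply(pair_steps, function(s) hc$labels[-hc$merge[s, ]])
  expect_true(any(vapply(leaf_pairs, setequal, logical(1),
                         c("hi1", "hi2"))))
  # the zero-threshold species attaches last
  last <- hc$merge[nrow(hc$merge), ]
  expect_true(any(last < 0) && "zero" %in% hc$labels[-last[last < 0]])
})

test_that("newick export round-trips and uses midpoint heights", {
  # two points at distance 4 merge at height 4, split at the midpoint
  m <- matrix(c(0, 4), nrow = 2, dimnames = list(c("A", "B"), NULL))
  tr <- centroid_cluster(cbind(m, matrix(0, 2, 7))[, 1:8])
  expect_equal(tree_to_newick(tr), "(A:2,B:2);")
  # round trip preserves topology and heights
  set.seed(3)
  m6 <- matrix(runif(6 * 8, 0, 100), nrow = 6,
               dimnames = list(paste0("sp", 1:6), NULL))
  tr6 <- centroid_cluster(m6)
  txt <- tree_to_newick(tr6)
  back <- ape::read.tree(text = txt)
  expect_setequal(back$tip.label, paste0("sp", 1:6))
  expect_equal(topology_distance(tr6, back), 0L)
  orig <- ape::as.phylo(tr6$hclust)
  expect_equal(stats::cophenetic(back)[orig$tip.label, orig$tip.label],
               stats::cophenetic(orig)[orig$tip.label, orig$tip.label],
               tolerance = 1e-6)
})

# independent bipartition-set oracle for the RF distance
rf_brute <- function(t1, t2) {
  bip <- function(tr) {
    tr <- ape::unroot(tr)
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    sets <- lapply(pp, function(i) sort(labs[i]))
    # nontrivial splits only, canonicalised by the side not containing tip 1
    sets <- Filter(function(s) length(s) >= 2 && length(s) <= length(labs) - 2,
                   lapply(sets, function(s) {
                     if (labs[1] %in% s) sort(setdiff(labs, s)) else s
                   }))
    unique(vapply(sets, paste, character(1), collapse = "|"))
  }
  b1 <- bip(t1); b2 <- bip(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

test_that("topology_distance equals the bipartition symmetric difference", {
  expect_equal(topology_distance("((A,B),(C,D));", "((A,B),(C,D));"), 0L)
  # caterpillar vs its mirror: identical unrooted topology
  cat1 <- "(((((A,B),C),D),E),F);"
  cat2 <- "(((((F,E),D),C),B),A);"
  expect_equal(topology_distance(cat1, cat2), 0L)
  set.seed(12)
  for (rep in 1:10) {
    t1 <- ape::rtree(6, tip.label = paste0("s", 1:6))
    t2 <- ape::rtree(6, tip.label = paste0("s", 1:6))
    expect_equal(topology_distance(t1, t2), rf_brute(t1, t2))
  }
  expect_error(topology_distance("((A,B),(C,D));", "((A,B),(C,E));"),
               "leaf-set mismatch")
})

test_that("distance matrices read and write through labelled CSV and Newick", {
  set.seed(2)
  labs <- paste0("sp", 1:5)
  D <- as.matrix(dist(matrix(rnorm(10), ncol = 2)))
  dimnames(D) <- list(labs, labs)
  f <- withr::local_tempfile(fileext = ".csv")
  write_distance_matrix(D, f)
  expect_equal(read_distance_matrix(f), D, tolerance = 1e-12)
  # patristic distances from a Newick file
  fn <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):2,C:3);", fn)
  Dp <- read_distance_matrix(fn)
  expect_equal(Dp["A", "B"], 2)
  expect_equal(Dp["A", "C"], 6)
})

test_that("the shipped synthetic phylogeny fixture is a valid placeholder", {
  f <- system.file("extdata", "synthetic_phylo_distances.csv",
                   package = "bkassay")
  expect_true(nzchar(f))
  D <- read_distance_matrix(f)
  expect_setequal(rownames(D), default_species_params()$species)
  expect_equal(D, t(D))
})
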