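# Gene-content distances, core-gene concatenation distances, and
# neighbor joining (exact on additive matrices; species monophyly on
# low-noise synthetic data).

test_that("jaccard and hamming distances match direct set arithmetic", {
  pm <- list(presence = matrix(c(1, 1, 0,
                                 0, 1, 1) == 1, nrow = 3,
                               dimnames = list(c("c1", "c2", "c3"), c("a", "b"))),
             counts = NULL, cluster_ids = c("c1", "c2", "c3"),
             genome_ids = c("a", "b"))
  class(pm) <- "pan_matrix"
  dj <- pan_matrix_distance(pm, "jaccard")
  expect_equal(dj["a", "b"], 1 - 1 / 3, tolerance = 1e-12)
  dh <- pan_matrix_distance(pm, "hamming")
  expect_equal(dh["a", "b"], 2 / 3, tolerance = 1e-12)
  expect_equal(diag(dj), c(a = 0, b = 0))

  # identical presence vectors are at distance zero under both metrics
  pm$presence <- cbind(pm$presence, a2 = pm$presence[, "a"])
  pm$genome_ids <- c("a", "b", "a2")
  d2 <- pan_matrix_distance(pm, "jaccard")
  expect_equal(d2["a", "a2"], 0)
})

test_that("jaccard distance agrees with vegan on a random fixture", {
  skip_if_not_installed("vegan")
  set.seed(41)
  pres <- matrix(runif(60) < 0.6, nrow = 10,
                 dimnames = list(sprintf("c%02d", 1:10), sprintf("g%d", 1:6)))
  pres[1, ] <- TRUE  # no empty genome
  pm <- structure(list(presence = pres, counts = NULL,
                       cluster_ids = rownames(pres), genome_ids = colnames(pres)),
                  class = "pan_matrix")
  got <- pan_matrix_distance(pm, "jaccard")
  ref <- as.matrix(vegan::vegdist(t(pres) * 1, method = "jaccard", binary = TRUE))
  expect_equal(got, ref[rownames(got), colnames(got)], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("jaccard rejects a genome with an empty presence set", {
  pres <- matrix(c(TRUE, FALSE, TRUE, FALSE) , nrow = 2,
                 dimnames = list(c("c1", "c2"), c("a", "b")))
  pres[, "b"] <- FALSE
  pm <- structure(list(presence = pres, counts = NULL,
                       cluster_ids = rownames(pres), genome_ids = colnames(pres)),
                  class = "pan_matrix")
  expect_error(pan_matrix_distance(pm, "jaccard"), "empty presence")
})

test_that("NJ recovers additive trees exactly (topology and branch lengths)", {
  skip_if_not_installed("phangorn")
  set.seed(42)
  for (i in 1:8) {
    ntax <- sample(4:8, 1)
    true <- ape::rtree(ntax, br = function(n) runif(n, 0.1, 1))
    d <- ape::cophenetic.phylo(true)
    got <- neighbor_joining(d)
    expect_equal(phangorn::RF.dist(ape::unroot(true), got), 0)
    # path distances reproduce the input matrix (additivity)
    dd <- ape::cophenetic.phylo(got)
    expect_equal(dd[rownames(d), colnames(d)], d, tolerance = 1e-8)
  }
})

test_that("three taxa give the closed-form star branch lengths", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  # x = (dab + dac - dbc)/2 etc.
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp["a", "b"], 3)
  expect_equal(cp["a", "c"], 4)
  expect_equal(cp["b", "c"], 5)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("NJ input validation and Newick round-trip", {
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(d), "at least 3")
  d3 <- matrix(runif(9), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(d3), "not symmetric")

  set.seed(43)
  true <- ape::rtree(6)
  f <- tempfile(fileext = ".nwk")
  write_newick(true, f)
  back <- ape::read.tree(f)
  expect_equal(ape::cophenetic.phylo(back)[true$tip.label, true$tip.label],
               ape::cophenetic.phylo(true)[true$tip.label, true$tip.label],
               tolerance = 1e-9)
})

test_that("core-gene concatenation distances behave as planted", {
  # identical genomes -> all-zero distances; fixed seed -> deterministic
  s <- replicate(5, rand_seq(200))
  gs <- toy_genome_set(list(
    a = list(species = "X", genes = setNames(s, paste0("f", 1:5))),
    b = list(species = "Y", genes = setNames(s, paste0("f", 1:5))),
    c = list(species = "Y", genes = setNames(s, paste0("f", 1:5)))), "X")
  cl <- greedy_cluster(gs)
  d0 <- core_concat_distance(gs, cl, n_clusters = 3, seed = 5)
  expect_true(all(d0 == 0))
  expect_identical(core_concat_distance(gs, cl, n_clusters = 3, seed = 5), d0)
  expect_error(core_concat_distance(gs, cl, n_clusters = 10, seed = 5),
               "single-copy core clusters")

  # two clades at ~10% divergence: between-clade p-distance near 0.1
  set.seed(44)
  anc <- replicate(6, rand_seq(300))
  cladeB <- vapply(anc, function(a) mutate_seq(a, 0.10), character(1))
  mk <- function(id, sp, seqs) list(species = sp,
                                    genes = setNames(seqs, paste0("f", 1:6)))
  gs2 <- toy_genome_set(list(
    a1 = mk("a1", "A", anc), a2 = mk("a2", "A", anc),
    b1 = mk("b1", "B", cladeB), b2 = mk("b2", "B", cladeB)), "A")
  cl2 <- greedy_cluster(gs2)
  d2 <- core_concat_distance(gs2, cl2, n_clusters = 6, seed = 6)
  expect_lt(abs(mean(d2[c("a1", "a2"), c("b1", "b2")]) - 0.095), 0.03)
  expect_equal(d2["a1", "a2"], 0)
})

test_that("species form clades on low-noise synthetic pan-matrices", {
  comm <- small_community(seed = 45)
  gs <- comm$genome_set
  cl <- greedy_cluster(gs)
  pm <- build_pan_matrix(cl, gs)
  tr <- suppressWarnings(neighbor_joining(pan_matrix_distance(pm, "jaccard")))
  labs <- split(names(gs$genomes),
                vapply(gs$genomes, `[[`, "", "species_label"))
  for (sp in names(labs))
    expect_true(ape::is.monophyletic(tr, labs[[sp]]),
                info = paste("gene-content tree, species", sp))
  # same check on the core-genome tree (planted tree is the species star,
  # so every species must be monophyletic)
  dc <- core_concat_distance(gs, cl, n_clusters = 10, seed = 46)
  trc <- suppressWarnings(neighbor_joining(dc))
  for (sp in names(labs))
    expect_true(ape::is.monophyletic(trc, labs[[sp]]),
                info = paste("core tree, species", sp))
})
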