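# Greedy centroid clustering: toy partitions, brute-force oracle
# equivalence, order independence, cutoff monotonicity, both alphabets.

make_family_set <- function(seed = 21, n_fam = 4, members_per = 3, len = 120,
                            within = 0.05) {
  # two genomes per "member slot" so ids differ; families well separated
  set.seed(seed)
  anc <- replicate(n_fam, rand_seq(len))
  genomes <- list()
  for (m in seq_len(members_per)) {
    genes <- setNames(vapply(anc, function(a) mutate_seq(a, within), character(1)),
                      sprintf("fam%02d", seq_len(n_fam)))
    genomes[[m]] <- genome_record(sprintf("g%02d", m),
                                  if (m == 1) "target" else "other", genes)
  }
  genome_set(genomes, "target")
}

test_that("toy partitions come out as expected", {
  s <- rand_seq(60)
  gs <- toy_genome_set(list(
    a = list(species = "X", genes = c(g1 = s)),
    b = list(species = "Y", genes = c(g1 = s, g2 = rand_seq(60)))), "X")
  cl <- greedy_cluster(gs, cutoff = 0.5)
  expect_equal(nrow(cl$clusters), 2L)
  expect_setequal(cl$clusters$size, c(2L, 1L))

  # all genes identical -> one cluster
  gs2 <- toy_genome_set(list(
    a = list(species = "X", genes = c(g1 = s, g2 = s)),
    b = list(species = "Y", genes = c(g1 = s))), "X")
  expect_equal(nrow(greedy_cluster(gs2, cutoff = 0.5)$clusters), 1L)

  # cutoff 1 on pairwise-distinct genes -> singletons
  set.seed(22)
  gs3 <- toy_genome_set(list(
    a = list(species = "X", genes = c(g1 = rand_seq(60), g2 = rand_seq(60))),
    b = list(species = "Y", genes = c(g1 = rand_seq(60)))), "X")
  expect_equal(nrow(greedy_cluster(gs3, cutoff = 1)$clusters), 3L)
})

test_that("every gene is assigned to exactly one cluster", {
  gs <- make_family_set()
  cl <- greedy_cluster(gs)
  n_genes <- sum(vapply(gs$genomes, function(g) length(g$genes), 1L))
  expect_equal(nrow(cl$members), n_genes)
  expect_equal(sum(cl$clusters$size), n_genes)
  expect_false(anyDuplicated(paste(cl$members$genome_id, cl$members$gene_id)) > 0)
})

test_that("clustering satisfies the oracle predicates (<= 30 genes)", {
  gs <- make_family_set(seed = 23, n_fam = 5, members_per = 3)
  cutoff <- 0.5
  cl <- greedy_cluster(gs, cutoff = cutoff)
  # brute-force all-pairs identity matrix, computed independently
  tab <- panmarker:::gene_table(gs)
  key <- paste(tab$genome_id, tab$gene_id)
  ids <- matrix(NA_real_, nrow(tab), nrow(tab), dimnames = list(key, key))
  for (i in seq_len(nrow(tab))) for (j in seq_len(nrow(tab)))
    ids[i, j] <- pairwise_identity(tab$seq[i], tab$seq[j])
  reps <- cl$clusters
  rep_key <- paste(reps$rep_genome_id, reps$rep_gene_id)
  # member identity to its representative reaches the cutoff
  mem <- merge(cl$members, reps, by = "cluster_id")
  for (r in seq_len(nrow(mem))) {
    expect_gte(ids[paste(mem$genome_id[r], mem$gene_id[r]),
                   paste(mem$rep_genome_id[r], mem$rep_gene_id[r])], cutoff)
    expect_equal(ids[paste(mem$genome_id[r], mem$gene_id[r]),
                     paste(mem$rep_genome_id[r], mem$rep_gene_id[r])],
                 mem$identity_to_rep[r])
  }
  # representatives are mutually separated below the cutoff
  if (length(rep_key) > 1) {
    sep <- ids[rep_key, rep_key]
    expect_true(all(sep[upper.tri(sep)] < cutoff))
  }
})

test_that("clustering is independent of input order", {
  gs <- make_family_set(seed = 24)
  cl1 <- greedy_cluster(gs)
  gs_perm <- gs
  gs_perm$genomes <- rev(gs_perm$genomes)
  gs_perm$genomes <- lapply(gs_perm$genomes, function(g) {
    g$genes <- rev(g$genes); g
  })
  cl2 <- greedy_cluster(gs_perm)
  expect_identical(cl1$members, cl2$members)
  expect_identical(cl1$clusters, cl2$clusters)
})

test_that("raising the cutoff never merges clusters", {
  gs <- make_family_set(seed = 25, n_fam = 4, members_per = 4, within = 0.12)
  ns <- vapply(c(0.3, 0.5, 0.7, 0.9), function(co)
    nrow(greedy_cluster(gs, cutoff = co)$clusters), 1L)
  expect_true(all(diff(ns) >= 0))
})

test_that("protein-mode clustering recovers the same families", {
  # lengths multiple of 3 so translation is clean
  set.seed(26)
  anc <- replicate(3, rand_seq(150))
  genomes <- lapply(1:3, function(m)
    genome_record(sprintf("g%d", m), if (m == 1) "t" else "o",
                  setNames(vapply(anc, function(a) mutate_seq(a, 0.03),
                                  character(1)),
                           c("f1", "f2", "f3"))))
  gs <- genome_set(genomes, "t")
  cln <- greedy_cluster(gs, mode = "nucleotide")
  clp <- greedy_cluster(gs, mode = "protein")
  expect_equal(nrow(clp$clusters), 3L)
  # same partition of genes (cluster labels may differ)
  keyn <- split(paste(cln$members$genome_id, cln$members$gene_id),
                cln$members$cluster_id)
  keyp <- split(paste(clp$members$genome_id, clp$members$gene_id),
                clp$members$cluster_id)
  expect_setequal(lapply(keyn, sort), lapply(keyp, sort))
})

test_that("cluster tables round-trip through TSV", {
  gs <- make_family_set(seed = 27)
  cl <- greedy_cluster(gs)
  f <- tempfile(fileext = ".tsv")
  write_cluster_table(cl, f)
  back <- read_cluster_table(f)
  expect_equal(nrow(back), nrow(cl$members))
  expect_setequal(unique(back$cluster_id), cl$clusters$cluster_id)
})
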