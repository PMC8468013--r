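# Shared fixtures and independent oracles used across the test files.

rand_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

# substitute each site with probability p (uniform over the other 3 bases)
mutate_seq <- function(seq, p) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < p)
  if (length(hit)) {
    v[hit] <- vapply(v[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  }
  paste(v, collapse = "")
}

# Independent slow oracle for global affine alignment: full-matrix DP over
# (score, matches, pairs) with the same lexicographic tie-break as the
# implementation, written directly from the recurrences. O(n*m) in R -- use
# on short sequences only.
oracle_nw <- function(a, b, match = 1, mismatch = -1, gap_open = 10, gap_ext = 1) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  new_layer <- function() list(s = matrix(NEG, n + 1, m + 1),
                               mt = matrix(0, n + 1, m + 1),
                               pr = matrix(0, n + 1, m + 1))
  M <- new_layer(); X <- new_layer(); Y <- new_layer()
  M$s[1, 1] <- 0
  for (i in seq_len(n)) X$s[i + 1, 1] <- -(gap_open + i * gap_ext)
  for (j in seq_len(m)) Y$s[1, j + 1] <- -(gap_open + j * gap_ext)
  best3 <- function(cands) {
    # cands: list of c(score, matches, pairs); lexicographic max
    k <- order(vapply(cands, `[`, 0, 1), vapply(cands, `[`, 0, 2),
               vapply(cands, `[`, 0, 3), decreasing = TRUE)[1]
    cands[[k]]
  }
  at <- function(L, i, j) c(L$s[i, j], L$mt[i, j], L$pr[i, j])
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      eq <- av[i - 1] == bv[j - 1] &&
        av[i - 1] %in% c("A", "C", "G", "T")
      sub <- if (eq) match else mismatch
      d <- best3(list(at(M, i - 1, j - 1), at(X, i - 1, j - 1), at(Y, i - 1, j - 1)))
      if (d[1] > NEG / 2) {
        M$s[i, j] <- d[1] + sub; M$mt[i, j] <- d[2] + eq; M$pr[i, j] <- d[3] + 1
      }
      x <- best3(list(at(M, i - 1, j) - c(gap_open + gap_ext, 0, 0),
                      at(X, i - 1, j) - c(gap_ext, 0, 0),
                      at(Y, i - 1, j) - c(gap_open + gap_ext, 0, 0)))
      X$s[i, j] <- x[1]; X$mt[i, j] <- x[2]; X$pr[i, j] <- x[3]
      y <- best3(list(at(M, i, j - 1) - c(gap_open + gap_ext, 0, 0),
                      at(X, i, j - 1) - c(gap_open + gap_ext, 0, 0),
                      at(Y, i, j - 1) - c(gap_ext, 0, 0)))
      Y$s[i, j] <- y[1]; Y$mt[i, j] <- y[2]; Y$pr[i, j] <- y[3]
    }
  }
  fin <- best3(list(at(M, n + 1, m + 1), at(X, n + 1, m + 1), at(Y, n + 1, m + 1)))
  list(score = fin[1], matches = fin[2], columns = n + m - fin[3],
       identity = fin[2] / (n + m - fin[3]))
}

# build a genome_set from a named list: list(genome_id = list(species =, genes =))
toy_genome_set <- function(spec, target) {
  genome_set(lapply(names(spec), function(g)
    genome_record(g, spec[[g]]$species, spec[[g]]$genes)), target)
}

# A small synthetic community with family structure, cheap enough for
# module-level tests (4 species, 9 genomes).
small_community <- function(seed = 42, ...) {
  generate_community(community_spec(
    n_species = 4, genomes_per_species = c(3L, 2L, 2L, 2L),
    n_core_genes = 12L, n_accessory_genes = 6L, n_unique_genes = 4L,
    gene_length_range = c(250L, 400L), marker_length = 700L,
    seed = seed, ...))
}

# Rand index between two partitions given as cluster label vectors
rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  same_x <- outer(x, x, "==")
  same_y <- outer(y, y, "==")
  ut <- upper.tri(same_x)
  mean(same_x[ut] == same_y[ut])
}
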