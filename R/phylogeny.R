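# Gene-content and core-gene phylogenies: distance matrices from the
# pan-matrix (Jaccard / Hamming on presence vectors) or from concatenated
# core-gene alignments (p-distance), then neighbor-joining to an unrooted
# tree serialized as Newick.

#' Gene-content distances between genomes
#'
#' Jaccard: `1 - |A intersect B| / |A union B|` over the presence sets of two
#' genomes; Hamming: fraction of clusters whose presence differs.
#'
#' @param pan_matrix a [build_pan_matrix()] result.
#' @param metric `"jaccard"` (default) or `"hamming"`.
#' @return square symmetric numeric matrix with genome ids as labels and a
#'   zero diagonal.
#' @export
pan_matrix_distance <- function(pan_matrix, metric = c("jaccard", "hamming")) {
  stopifnot(inherits(pan_matrix, "pan_matrix"))
  metric <- match.arg(metric)
  pres <- pan_matrix$presence
  m <- `+`(pres, 0)
  inter <- crossprod(m)                      # |A n B|
  sizes <- diag(inter)
  if (metric == "jaccard") {
    if (any(sizes == 0))
      stop("genome with empty presence set: Jaccard undefined for ",
           paste(colnames(m)[sizes == 0], collapse = ", "), call. = FALSE)
    un <- outer(sizes, sizes, "+") - inter   # |A u B|
    d <- 1 - inter / un
  } else {
    d <- (outer(sizes, sizes, "+") - 2 * inter) / nrow(pres)
  }
  diag(d) <- 0
  dimnames(d) <- list(colnames(m), colnames(m))
  d
}

#' Distances from concatenated single-copy core-gene alignments
#'
#' Samples `n_clusters` single-copy core clusters (exactly one member in
#' every genome) with the given seed, aligns each member to the cluster
#' representative, projects it onto the representative's coordinates,
#' concatenates the per-genome rows across clusters, and returns the
#' p-distance (mismatching columns / compared columns; columns where either
#' genome has a gap are excluded).
#'
#' @param genome_set,clustering the genome set and its clustering.
#' @param n_clusters number of clusters to sample (default 20).
#' @param seed integer seed making the "random" cluster sample reproducible.
#' @param scoring alignment scoring overrides, see [pairwise_identity()].
#' @return square symmetric numeric matrix over genome ids.
#' @export
core_concat_distance <- function(genome_set, clustering, n_clusters = 20L,
                                 seed, scoring = list()) {
  stopifnot(inherits(genome_set, "genome_set"),
            inherits(clustering, "clustering_result"), n_clusters >= 1L)
  genome_ids <- names(genome_set$genomes)
  members <- clustering$members
  per <- table(members$cluster_id, members$genome_id)
  single_copy <- rownames(per)[apply(per == 1L, 1L, all)]
  if (length(single_copy) < n_clusters)
    stop(sprintf(paste0("only %d single-copy core clusters available, ",
                        "%d requested"), length(single_copy), n_clusters),
         call. = FALSE)
  chosen <- with_seed(seed, sort(sample(single_copy, n_clusters)))
  rows <- lapply(chosen, function(cid) {
    rep_seq <- cluster_rep_seq(clustering, genome_set, cid)
    mem <- members[members$cluster_id == cid, ]
    block <- matrix("-", nrow = length(genome_ids), ncol = nchar(rep_seq),
                    dimnames = list(genome_ids, NULL))
    for (i in seq_len(nrow(mem))) {
      s <- gene_seq(genome_set, mem$genome_id[i], mem$gene_id[i])
      if (identical(s, rep_seq)) {
        block[mem$genome_id[i], ] <- strsplit(rep_seq, "", fixed = TRUE)[[1]]
      } else if (nchar(s) == nchar(rep_seq) &&
                 mean(strsplit(s, "", fixed = TRUE)[[1]] ==
                      strsplit(rep_seq, "", fixed = TRUE)[[1]]) >= 0.5) {
        # equal-length, high-identity pair: under the stiff default gap
        # penalties the optimal global alignment is gapless, so the
        # projection is the sequence itself
        block[mem$genome_id[i], ] <- strsplit(s, "", fixed = TRUE)[[1]]
      } else {
        al <- pairwise_alignment(s, rep_seq, scoring = scoring)
        keep <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]] != "-"
        block[mem$genome_id[i], ] <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]][keep]
      }
    }
    block
  })
  aln <- do.call(cbind, rows)
  n <- length(genome_ids)
  d <- matrix(0, n, n, dimnames = list(genome_ids, genome_ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    a <- aln[i, ]; b <- aln[j, ]
    ok <- a != "-" & b != "-"
    if (!any(ok)) stop("no comparable columns between ", genome_ids[i],
                       " and ", genome_ids[j], call. = FALSE)
    d[i, j] <- d[j, i] <- sum(a[ok] != b[ok]) / sum(ok)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou–Nei neighbor joining (exact on additive matrices) with
#' genome labels put in canonical order first, so the result is deterministic
#' for a given matrix. Negative branch-length estimates are clamped to zero
#' with a warning, the standard practice.
#'
#' @param d square symmetric numeric matrix (zero diagonal, >= 3 labels).
#' @return an [ape::phylo] unrooted tree.
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3L) stop("need at least 3 labels", call. = FALSE)
  if (is.null(rownames(d))) stop("distance matrix must be labeled", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix is not symmetric", call. = FALSE)
  if (any(!is.finite(d)) || any(d < 0))
    stop("distances must be finite and non-negative", call. = FALSE)
  ord <- order(rownames(d), method = "radix")
  d <- d[ord, ord]
  tree <- ape::nj(as.dist(d))
  if (any(tree$edge.length < 0)) {
    warning(sum(tree$edge.length < 0),
            " negative NJ branch length(s) clamped to zero")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Write a tree as Newick
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a labeled square distance matrix as TSV
#'
#' @param d square matrix with labels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(genome_id = rownames(d), d, check.names = FALSE)
  write_tsv(df, path)
}
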