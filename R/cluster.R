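# Greedy centroid (UCLUST-style) ortholog clustering at an identity cutoff.
#
# Genes from all genomes are canonically ordered (length descending, then
# genome id, then gene id), so the result is independent of input file order.
# Each gene is compared to existing cluster representatives in descending
# shared-k-mer order (ties: earlier-founded representative first) and joins
# the first one whose alignment identity reaches the cutoff; after
# `maxrejects` failed alignments the gene founds a new cluster with itself as
# representative. Pairs whose lengths alone prove the cutoff unreachable are
# skipped for free.

#' Cluster all genes of a genome set into ortholog clusters
#'
#' @param genome_set a [genome_set()].
#' @param cutoff identity cutoff in `(0, 1]`; default `0.5`, the USEARCH
#'   default used for bacterial pan-genome clustering.
#' @param mode `"nucleotide"` (default; keeps coordinates usable for primer
#'   design) or `"protein"` (genes translated, frame 0, before clustering).
#' @param k k-mer size for candidate ordering (default 8).
#' @param maxrejects maximum failed alignments per gene before it founds a
#'   new cluster (default 8, the UCLUST default; `Inf` examines every representative).
#' @param scoring alignment scoring overrides, see [pairwise_identity()].
#' @return object of class `clustering_result`: list with
#'   \describe{
#'     \item{members}{data.frame `cluster_id`, `genome_id`, `gene_id`,
#'       `identity_to_rep`, `is_representative`, one row per gene.}
#'     \item{clusters}{data.frame `cluster_id`, `rep_genome_id`,
#'       `rep_gene_id`, `size`, `within_identity_min`, `within_identity_max`.}
#'     \item{cutoff, mode}{the parameters used.}
#'   }
#' @examples
#' gs <- genome_set(list(
#'   genome_record("g1", "A", c(x = "ACGTACGTACGTACGT")),
#'   genome_record("g2", "B", c(y = "ACGTACGTACGTACGT"))), "A")
#' greedy_cluster(gs, cutoff = 0.5)
#' @export
greedy_cluster <- function(genome_set, cutoff = 0.5, mode = c("nucleotide", "protein"),
                           k = 8L, maxrejects = 8L, scoring = list()) {
  stopifnot(inherits(genome_set, "genome_set"), cutoff > 0, cutoff <= 1)
  mode <- match.arg(mode)
  sc <- check_scoring(scoring)
  tab <- gene_table(genome_set)
  if (nrow(tab) == 0L) stop("genome set contains no genes", call. = FALSE)
  seqs <- tab$seq
  if (mode == "protein") seqs <- translate_cds(seqs)
  # canonical order: length desc, then genome_id, gene_id (radix = C locale)
  ord <- order(-nchar(seqs), tab$genome_id, tab$gene_id, method = "radix")
  tab <- tab[ord, ]
  seqs <- seqs[ord]
  mr <- if (is.finite(maxrejects)) as.integer(maxrejects) else .Machine$integer.max
  res <- .greedy_cluster_cpp(seqs, cutoff, as.integer(k), mr,
                             sc$match, sc$mismatch, sc$gap_open, sc$gap_extend,
                             mode == "nucleotide")
  n_clust <- length(res$representative)
  cluster_id <- sprintf("C%05d", res$cluster)
  members <- data.frame(cluster_id = cluster_id,
                        genome_id = tab$genome_id,
                        gene_id = tab$gene_id,
                        identity_to_rep = res$identity,
                        is_representative = seq_len(nrow(tab)) %in% res$representative,
                        stringsAsFactors = FALSE)
  members <- members[order(members$cluster_id, members$genome_id, members$gene_id,
                           method = "radix"), ]
  rownames(members) <- NULL
  rep_rows <- tab[res$representative, ]
  agg_min <- tapply(members$identity_to_rep, members$cluster_id, min)
  agg_max <- tapply(members$identity_to_rep, members$cluster_id, max)
  sizes <- tapply(members$identity_to_rep, members$cluster_id, length)
  cid <- sprintf("C%05d", seq_len(n_clust))
  clusters <- data.frame(cluster_id = cid,
                         rep_genome_id = rep_rows$genome_id,
                         rep_gene_id = rep_rows$gene_id,
                         size = as.integer(sizes[cid]),
                         within_identity_min = as.numeric(agg_min[cid]),
                         within_identity_max = as.numeric(agg_max[cid]),
                         stringsAsFactors = FALSE)
  rownames(clusters) <- NULL
  out <- list(members = members, clusters = clusters, cutoff = cutoff,
              mode = mode, k = as.integer(k), maxrejects = maxrejects,
              scoring = sc)
  class(out) <- "clustering_result"
  out
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf(paste0("<clustering_result> %d genes in %d clusters ",
                     "(cutoff %.2f, %s mode)\n"),
              nrow(x$members), nrow(x$clusters), x$cutoff, x$mode))
  sz <- table(x$clusters$size)
  cat("  cluster sizes: ",
      paste(sprintf("%sx%s", sz, names(sz)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# flat gene table of a genome set
gene_table <- function(genome_set) {
  parts <- lapply(genome_set$genomes, function(g)
    data.frame(genome_id = g$genome_id, gene_id = names(g$genes),
               seq = unname(g$genes), stringsAsFactors = FALSE))
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

# sequence of one gene
gene_seq <- function(genome_set, genome_id, gene_id) {
  g <- genome_set$genomes[[genome_id]]
  if (is.null(g)) stop("unknown genome '", genome_id, "'", call. = FALSE)
  s <- g$genes[[gene_id]]
  if (is.null(s)) stop("unknown gene '", gene_id, "' in genome '", genome_id, "'",
                       call. = FALSE)
  s
}

# representative sequence of a cluster (nucleotide)
cluster_rep_seq <- function(clustering, genome_set, cluster_id) {
  row <- clustering$clusters[clustering$clusters$cluster_id == cluster_id, ]
  if (nrow(row) != 1L) stop("unknown cluster '", cluster_id, "'", call. = FALSE)
  gene_seq(genome_set, row$rep_genome_id, row$rep_gene_id)
}

#' Write / read the cluster membership table
#'
#' TSV with columns `cluster_id`, `rep_genome_id`, `rep_gene_id`,
#' `genome_id`, `gene_id`, `identity_to_rep`.
#'
#' @param clustering a `clustering_result`.
#' @param path output path.
#' @return `path` invisibly (`write`), or the table as a data.frame (`read`).
#' @export
write_cluster_table <- function(clustering, path) {
  reps <- clustering$clusters[, c("cluster_id", "rep_genome_id", "rep_gene_id")]
  df <- merge(clustering$members, reps, by = "cluster_id", sort = FALSE)
  df <- df[order(df$cluster_id, df$genome_id, df$gene_id, method = "radix"),
           c("cluster_id", "rep_genome_id", "rep_gene_id",
             "genome_id", "gene_id", "identity_to_rep")]
  write_tsv(df, path)
}

#' @rdname write_cluster_table
#' @export
read_cluster_table <- function(path) {
  read_tsv(path)
}
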