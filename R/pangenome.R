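# Pan-genome structure: the clusters x genomes count/presence matrix and its
# partition into core, accessory and singleton ("unique") clusters.
#
# Terminology note: "unique" here is the pan-genome sense (a cluster confined
# to exactly one genome). The clade-specific marker of the screening stage —
# a cluster confined to all genomes of one species — is a different notion
# and lives in the marker screen.

#' Build the clusters x genomes pan-matrix
#'
#' `counts[c, g]` is the number of members of cluster `c` contributed by
#' genome `g` (paralogs counted); `presence` is `counts >= 1`.
#'
#' @param clustering a `clustering_result` covering every gene of the set.
#' @param genome_set the [genome_set()] the clustering was computed on.
#' @return object of class `pan_matrix`: list with integer matrix `counts`,
#'   logical matrix `presence` (rows: clusters, columns: genomes in genome-set
#'   order), `cluster_ids`, `genome_ids`.
#' @export
build_pan_matrix <- function(clustering, genome_set) {
  stopifnot(inherits(clustering, "clustering_result"),
            inherits(genome_set, "genome_set"))
  members <- clustering$members
  if (nrow(members) == 0L || nrow(clustering$clusters) == 0L)
    stop("empty clustering", call. = FALSE)
  genome_ids <- names(genome_set$genomes)
  unknown <- setdiff(unique(members$genome_id), genome_ids)
  if (length(unknown))
    stop("clustering refers to genomes absent from the set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (g in genome_ids) {
    have <- members$gene_id[members$genome_id == g]
    miss <- setdiff(have, names(genome_set$genomes[[g]]$genes))
    if (length(miss))
      stop("clustering refers to genes absent from genome '", g, "': ",
           paste(head(miss, 5), collapse = ", "), call. = FALSE)
  }
  cluster_ids <- clustering$clusters$cluster_id
  counts <- table(factor(members$cluster_id, levels = cluster_ids),
                  factor(members$genome_id, levels = genome_ids))
  counts <- matrix(as.integer(counts), nrow = length(cluster_ids),
                   dimnames = list(cluster_ids, genome_ids))
  out <- list(counts = counts, presence = counts >= 1L,
              cluster_ids = cluster_ids, genome_ids = genome_ids)
  class(out) <- "pan_matrix"
  out
}

#' @export
print.pan_matrix <- function(x, ...) {
  cat(sprintf("<pan_matrix> %d clusters x %d genomes (%d genes)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Partition the pan-genome into core, accessory and unique clusters
#'
#' Core clusters are present in every genome, unique (singleton) clusters in
#' exactly one, accessory clusters in between. With a single genome every
#' cluster is simultaneously core and unique; it is reported as core.
#'
#' @param pan_matrix a [build_pan_matrix()] result.
#' @return object of class `pan_partition`: list with character vectors
#'   `core`, `accessory`, `unique` and integer `pan_size`.
#' @export
pan_partition <- function(pan_matrix) {
  stopifnot(inherits(pan_matrix, "pan_matrix"))
  pres <- pan_matrix$presence
  n_genomes <- ncol(pres)
  stopifnot(n_genomes >= 1L)
  n_present <- rowSums(pres)
  core <- rownames(pres)[n_present == n_genomes]
  uniq <- setdiff(rownames(pres)[n_present == 1L], core)
  acc <- setdiff(rownames(pres), c(core, uniq))
  out <- list(core = core, accessory = acc, unique = uniq,
              pan_size = nrow(pres))
  class(out) <- "pan_partition"
  out
}

#' @export
print.pan_partition <- function(x, ...) {
  cat(sprintf("<pan_partition> pan %d = core %d + accessory %d + unique %d\n",
              x$pan_size, length(x$core), length(x$accessory), length(x$unique)))
  invisible(x)
}

#' Write / read the presence matrix and partition summary
#'
#' `write_pan_matrix` writes the 0/1 presence matrix as TSV (clusters in
#' rows); `write_pan_partition` writes one row per cluster with its class.
#'
#' @param pan_matrix a `pan_matrix`; `partition` a `pan_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pan_matrix <- function(pan_matrix, path) {
  df <- data.frame(cluster_id = rownames(pan_matrix$presence),
                   `+`(pan_matrix$presence, 0L), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_pan_matrix
#' @param partition a `pan_partition`.
#' @export
write_pan_partition <- function(partition, path) {
  df <- rbind(
    data.frame(cluster_id = partition$core, class = "core"),
    data.frame(cluster_id = partition$accessory, class = "accessory"),
    data.frame(cluster_id = partition$unique, class = "unique"))
  df <- df[order(df$cluster_id, method = "radix"), ]
  write_tsv(df, path)
}
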