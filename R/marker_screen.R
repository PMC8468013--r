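# The clade-specificity screen: clusters present in every target-clade
# genome with high within-clade identity, absent from every non-target
# genome, and — after an explicit cross-homology alignment scan against all
# non-target genes — without any non-target homolog at or above the exclusion
# threshold. Survivors are ranked by primer-design suitability (GC content
# and length).

#' Screen configuration
#'
#' @param target_species species label to screen for; if `NULL`, taken from
#'   the genome set at screen time.
#' @param within_identity_min minimum identity of every target member to the
#'   cluster representative (default 0.94, the lower end of the within-clade
#'   identity range a clade-unique gene is expected to show).
#' @param cross_identity_max candidates with a non-target hit at or above
#'   this identity are excluded (default 0.50, the clustering cutoff).
#' @param homology_report_floor hits below this identity are reported as
#'   "below floor" rather than by value (default 0.30); the scan may skip
#'   alignments that provably cannot reach the floor.
#' @param gc_ideal,length_ideal ideal intervals for the representative's GC
#'   fraction (default `[0.40, 0.60]`) and length in nt
#'   (default `[300, 2000]`; long enough for a ~130 bp product plus primer
#'   flanks, short enough to be a typical single gene).
#' @param w_gc,w_len penalty weights of the two ranking terms (default 1 each).
#' @return object of class `screen_config`.
#' @export
screen_config <- function(target_species = NULL, within_identity_min = 0.94,
                          cross_identity_max = 0.50, homology_report_floor = 0.30,
                          gc_ideal = c(0.40, 0.60), length_ideal = c(300, 2000),
                          w_gc = 1, w_len = 1) {
  stopifnot(within_identity_min > 0, within_identity_min <= 1,
            cross_identity_max > 0, cross_identity_max <= within_identity_min,
            homology_report_floor > 0, homology_report_floor <= cross_identity_max,
            length(gc_ideal) == 2L, gc_ideal[1] < gc_ideal[2],
            length(length_ideal) == 2L, length_ideal[1] < length_ideal[2],
            w_gc >= 0, w_len >= 0)
  out <- list(target_species = target_species,
              within_identity_min = within_identity_min,
              cross_identity_max = cross_identity_max,
              homology_report_floor = homology_report_floor,
              gc_ideal = gc_ideal, length_ideal = length_ideal,
              w_gc = w_gc, w_len = w_len)
  class(out) <- "screen_config"
  out
}

screen_target <- function(config, genome_set) {
  ts <- config$target_species
  if (is.null(ts)) ts <- genome_set$target_species
  ts
}

#' Clusters shared by the whole target clade and absent elsewhere
#'
#' Stage one of the screen: clusters with presence in all target genomes,
#' no member in any non-target genome, and every target member's identity to
#' the representative at least `within_identity_min`.
#'
#' @param pan_matrix,clustering,genome_set pipeline objects.
#' @param config a [screen_config()].
#' @return character vector of cluster ids.
#' @export
shared_target_clusters <- function(pan_matrix, clustering, genome_set,
                                   config = screen_config()) {
  stopifnot(inherits(pan_matrix, "pan_matrix"),
            inherits(clustering, "clustering_result"),
            inherits(genome_set, "genome_set"))
  ts <- screen_target(config, genome_set)
  labs <- species_labels(genome_set)
  targets <- names(genome_set$genomes)[labs == ts]
  if (length(targets) == 0L)
    stop("no genome carries target species '", ts, "'", call. = FALSE)
  others <- setdiff(names(genome_set$genomes), targets)
  pres <- pan_matrix$presence
  hit <- rownames(pres)[rowSums(pres[, targets, drop = FALSE]) == length(targets) &
                        rowSums(pres[, others, drop = FALSE]) == 0L]
  # identity condition on target members
  keep <- vapply(hit, function(cid) {
    mem <- clustering$members[clustering$members$cluster_id == cid &
                              clustering$members$genome_id %in% targets, ]
    all(mem$identity_to_rep >= config$within_identity_min)
  }, logical(1))
  sort(hit[keep])
}

#' Cross-homology scan of candidate clusters against all non-target genes
#'
#' Stage two: each candidate's representative is aligned against every
#' non-target gene (after the conservative k-mer/length prefilter; alignments
#' that provably cannot reach the current best hit or the report floor are
#' skipped). Candidates whose best non-target identity reaches
#' `cross_identity_max` are dropped; for the rest the best hit is reported,
#' or flagged `below_floor` when no hit reaches `homology_report_floor`.
#'
#' @param cluster_ids candidates from [shared_target_clusters()].
#' @param clustering,genome_set pipeline objects.
#' @param config a [screen_config()].
#' @param scoring alignment scoring overrides, see [pairwise_identity()].
#' @return data.frame, one row per retained candidate: `cluster_id`,
#'   `rep_genome_id`, `rep_gene_id`, `gc`, `length_nt`, `max_cross_identity`
#'   (NA when below floor), `below_floor`, `best_hit_genome`, `best_hit_gene`.
#' @export
cross_homology_scan <- function(cluster_ids, clustering, genome_set,
                                config = screen_config(), scoring = list()) {
  stopifnot(inherits(clustering, "clustering_result"),
            inherits(genome_set, "genome_set"))
  ts <- screen_target(config, genome_set)
  labs <- species_labels(genome_set)
  others <- names(genome_set$genomes)[labs != ts]
  tab <- gene_table(genome_set)
  tab <- tab[tab$genome_id %in% others, ]
  tab$len <- nchar(tab$seq)
  # longest first so the running-max prune bites early
  tab <- tab[order(-tab$len, tab$genome_id, tab$gene_id, method = "radix"), ]
  rows <- lapply(cluster_ids, function(cid) {
    rep_seq <- cluster_rep_seq(clustering, genome_set, cid)
    lr <- nchar(rep_seq)
    best <- -Inf; best_g <- NA_character_; best_gene <- NA_character_
    for (i in seq_len(nrow(tab))) {
      bound <- min(tab$len[i], lr) / max(tab$len[i], lr)  # identity upper bound
      if (bound < config$homology_report_floor || bound <= best) next
      if (!kmer_prefilter(rep_seq, tab$seq[i],
                          cutoff = max(config$homology_report_floor, best)))
        next
      id <- pairwise_identity(rep_seq, tab$seq[i], scoring = scoring)
      if (id > best) {
        best <- id; best_g <- tab$genome_id[i]; best_gene <- tab$gene_id[i]
      }
    }
    below <- !is.finite(best) || best < config$homology_report_floor
    data.frame(cluster_id = cid,
               max_cross_identity = if (below) NA_real_ else best,
               below_floor = below,
               best_hit_genome = if (below) NA_character_ else best_g,
               best_hit_gene = if (below) NA_character_ else best_gene,
               excluded = is.finite(best) && best >= config$cross_identity_max,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- data.frame(cluster_id = character(0),
                                      max_cross_identity = numeric(0),
                                      below_floor = logical(0),
                                      best_hit_genome = character(0),
                                      best_hit_gene = character(0),
                                      excluded = logical(0))
  reps <- clustering$clusters[match(res$cluster_id, clustering$clusters$cluster_id), ]
  res$rep_genome_id <- reps$rep_genome_id
  res$rep_gene_id <- reps$rep_gene_id
  rep_seqs <- mapply(function(g, gn) gene_seq(genome_set, g, gn),
                     res$rep_genome_id, res$rep_gene_id)
  res$gc <- if (nrow(res)) compute_gc(unlist(rep_seqs)) else numeric(0)
  res$length_nt <- if (nrow(res)) nchar(unlist(rep_seqs)) else integer(0)
  kept <- res[!res$excluded, setdiff(names(res), "excluded")]
  rownames(kept) <- NULL
  kept
}

#' Rank marker candidates by primer-design suitability
#'
#' `rank_score = w_gc * gc_penalty + w_len * len_penalty`, where each penalty
#' is the (normalised) distance of the representative's GC fraction / length
#' from its ideal interval (zero inside the interval; length distances are
#' divided by the violated bound so the two terms are on comparable scales).
#' Candidates are sorted by ascending score, ties broken by `cluster_id`.
#'
#' @param candidates data.frame from [cross_homology_scan()].
#' @param config a [screen_config()].
#' @return the same data.frame with `gc_penalty`, `len_penalty`,
#'   `rank_score`, sorted best-first.
#' @export
rank_candidates <- function(candidates, config = screen_config()) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("no clade-specific marker found", call. = FALSE)
  gc_lo <- config$gc_ideal[1]; gc_hi <- config$gc_ideal[2]
  len_lo <- config$length_ideal[1]; len_hi <- config$length_ideal[2]
  candidates$gc_penalty <- pmax(0, gc_lo - candidates$gc,
                                candidates$gc - gc_hi)
  candidates$len_penalty <- pmax(0, (len_lo - candidates$length_nt) / len_lo,
                                 (candidates$length_nt - len_hi) / len_hi)
  candidates$rank_score <- config$w_gc * candidates$gc_penalty +
    config$w_len * candidates$len_penalty
  ord <- order(candidates$rank_score, candidates$cluster_id, method = "radix")
  out <- candidates[ord, ]
  rownames(out) <- NULL
  out
}

#' Run the full clade-specific marker screen
#'
#' Combines [shared_target_clusters()], [cross_homology_scan()] and
#' [rank_candidates()]; the top-ranked candidate is the selected marker.
#'
#' @inheritParams shared_target_clusters
#' @param scoring alignment scoring overrides.
#' @return object of class `screen_report`: list with `shared_in_target`
#'   (cluster ids), `ranked` (candidate table, best first), `selected`
#'   (top row), `config`.
#' @export
screen_markers <- function(pan_matrix, clustering, genome_set,
                           config = screen_config(), scoring = list()) {
  shared <- shared_target_clusters(pan_matrix, clustering, genome_set, config)
  if (length(shared) == 0L)
    stop("no clade-specific marker found: no cluster is present in all ",
         "target genomes and absent from all others", call. = FALSE)
  cand <- cross_homology_scan(shared, clustering, genome_set, config, scoring)
  ranked <- rank_candidates(cand, config)
  out <- list(shared_in_target = shared, ranked = ranked,
              selected = ranked[1L, ], config = config,
              target_species = screen_target(config, genome_set))
  class(out) <- "screen_report"
  out
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> target '%s': %d shared clusters, %d passed homology\n",
              x$target_species, length(x$shared_in_target), nrow(x$ranked)))
  s <- x$selected
  cross <- if (isTRUE(s$below_floor)) {
    sprintf("< %.2f (floor)", x$config$homology_report_floor)
  } else sprintf("%.3f vs %s", s$max_cross_identity, s$best_hit_genome)
  cat(sprintf("  selected %s (rep %s/%s, %d nt, GC %.2f, cross-identity %s)\n",
              s$cluster_id, s$rep_genome_id, s$rep_gene_id, s$length_nt,
              s$gc, cross))
  invisible(x)
}

#' Write the screen report table
#'
#' @param report a `screen_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(report, path) {
  df <- report$ranked
  df$selected <- df$cluster_id == report$selected$cluster_id
  write_tsv(df, path)
}
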