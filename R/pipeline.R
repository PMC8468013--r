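# End-to-end orchestration: ingest (or simulate) -> cluster -> pan-matrix ->
# partition -> phylogeny -> marker screen -> primer design + in-silico
# validation -> qPCR standard-curve analysis, from one config, with every
# artifact written as TSV/Newick/FASTA and the config echoed as YAML.

#' Build a run configuration
#'
#' Either `input` (real data: per-genome gene FASTAs + species table) or
#' `simulate` (a [community_spec()]) must be given. Every random choice in a
#' run is governed by an explicit seed: the community seed, the core-gene
#' sampling seed (`phylogeny$seed`, default derived as `seed + 1`) and the
#' qPCR simulation seed (`qpcr$seed`, default `seed + 2`).
#'
#' @param seed master integer seed.
#' @param input list with `fasta_paths` (named character vector),
#'   `species_table` (path) and `target_species`; or `NULL`.
#' @param simulate a [community_spec()] (its `seed` defaults to the master
#'   seed); or `NULL`.
#' @param clustering list of [greedy_cluster()] arguments
#'   (`cutoff`, `mode`, `k`, `maxrejects`, `scoring`).
#' @param screen a [screen_config()].
#' @param phylogeny list: `n_clusters` (default 20), `seed`, `metric`
#'   (default "jaccard"), `build_core_tree` (default TRUE).
#' @param primers list: `constraints` (a [primer_constraints()]),
#'   `max_mismatch` (2), `clamp` (3), `max_product` (3000), `n_max` (100).
#' @param qpcr list: either `observations` (path to a `log10_conc`/`ct` TSV)
#'   or simulation parameters `true_slope` (-3.530), `true_intercept`
#'   (36.906), `log10_concs` (3:9), `noise_sd` (0.1), `seed`.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, input = NULL, simulate = NULL,
                       clustering = list(), screen = screen_config(),
                       phylogeny = list(), primers = list(), qpcr = list()) {
  if (is.null(input) && is.null(simulate))
    simulate <- community_spec(seed = seed)
  if (!is.null(input))
    stopifnot(is.list(input),
              all(c("fasta_paths", "species_table", "target_species") %in%
                    names(input)))
  if (!is.null(simulate)) stopifnot(inherits(simulate, "community_spec"))
  clustering <- modifyList(list(cutoff = 0.5, mode = "nucleotide", k = 8L,
                                maxrejects = 8L, scoring = list()), clustering)
  phylogeny <- modifyList(list(n_clusters = 20L, seed = seed + 1L,
                               metric = "jaccard", build_core_tree = TRUE),
                          phylogeny)
  primers <- modifyList(list(constraints = primer_constraints(),
                             max_mismatch = 2L, clamp = 3L,
                             max_product = 3000L, n_max = 100L), primers)
  qpcr <- modifyList(list(true_slope = -3.530, true_intercept = 36.906,
                          log10_concs = 3:9, noise_sd = 0.1,
                          seed = seed + 2L, observations = NULL), qpcr)
  stopifnot(inherits(screen, "screen_config"))
  out <- list(seed = as.integer(seed), input = input, simulate = simulate,
              clustering = clustering, screen = screen, phylogeny = phylogeny,
              primers = primers, qpcr = qpcr)
  class(out) <- "run_config"
  out
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors the [run_config()] arguments; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "input", "simulate", "clustering", "screen", "phylogeny",
             "primers", "qpcr")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
  simulate <- if (!is.null(y$simulate)) {
    args <- y$simulate
    if (is.null(args$seed)) args$seed <- seed
    do.call(community_spec, args)
  }
  screen <- if (is.null(y$screen)) screen_config() else do.call(screen_config, y$screen)
  primers <- y$primers
  if (!is.null(primers$constraints))
    primers$constraints <- do.call(primer_constraints, primers$constraints)
  run_config(seed = seed, input = y$input, simulate = simulate,
             clustering = if (is.null(y$clustering)) list() else y$clustering,
             screen = screen,
             phylogeny = if (is.null(y$phylogeny)) list() else y$phylogeny,
             primers = if (is.null(primers)) list() else primers,
             qpcr = if (is.null(y$qpcr)) list() else y$qpcr)
}

stage <- function(name, verbose, code) {
  if (verbose) message(sprintf("[%s] ...", name))
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(code), error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  if (verbose)
    message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full marker-discovery pipeline
#'
#' Executes every stage in order, writes all artifacts under `outdir`
#' (config echo, per-genome FASTAs for simulated data, cluster table,
#' presence matrix + partition, distance matrices + Newick trees, screen
#' report, marker FASTA, primer table, specificity report, qPCR observations
#' + fit), and returns a run report. Any stage failure aborts with the stage
#' name in the error.
#'
#' @param config a [run_config()] (or a YAML path).
#' @param outdir output directory, created if needed; `NULL` runs in a
#'   temporary directory.
#' @param verbose emit per-stage log lines (default TRUE).
#' @return object of class `run_report`: list with `summary` (named list of
#'   headline numbers), the main result objects, and `paths` to artifacts.
#' @export
run_pipeline <- function(config, outdir = NULL, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(outdir)) outdir <- tempfile("panmarker_run_")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  echo_config(config, file.path(outdir, "config.yaml"))

  community <- NULL
  gs <- stage("ingest", verbose, {
    if (!is.null(config$input)) {
      inp <- config$input
      read_genome_set(unlist(inp$fasta_paths), inp$species_table,
                      inp$target_species)
    } else {
      community <- generate_community(config$simulate)
      write_community(community, file.path(outdir, "community"))
      community$genome_set
    }
  })

  clustering <- stage("cluster", verbose, {
    cl <- config$clustering
    res <- greedy_cluster(gs, cutoff = cl$cutoff, mode = cl$mode, k = cl$k,
                          maxrejects = cl$maxrejects, scoring = cl$scoring)
    write_cluster_table(res, file.path(outdir, "clusters.tsv"))
    res
  })

  pm <- stage("pan_matrix", verbose, {
    res <- build_pan_matrix(clustering, gs)
    write_pan_matrix(res, file.path(outdir, "pan_presence.tsv"))
    res
  })
  part <- stage("partition", verbose, {
    res <- pan_partition(pm)
    write_pan_partition(res, file.path(outdir, "pan_partition.tsv"))
    res
  })

  trees <- stage("phylogeny", verbose, {
    ph <- config$phylogeny
    d_pan <- pan_matrix_distance(pm, metric = ph$metric)
    write_distance_matrix(d_pan, file.path(outdir, "dist_pan.tsv"))
    t_pan <- neighbor_joining(d_pan)
    write_newick(t_pan, file.path(outdir, "tree_pan.nwk"))
    t_core <- NULL
    if (isTRUE(ph$build_core_tree)) {
      n_sc <- sum(apply(table(clustering$members$cluster_id,
                              clustering$members$genome_id) == 1L, 1L, all))
      if (n_sc >= ph$n_clusters) {
        d_core <- core_concat_distance(gs, clustering, ph$n_clusters,
                                       seed = ph$seed)
        write_distance_matrix(d_core, file.path(outdir, "dist_core.tsv"))
        t_core <- neighbor_joining(d_core)
        write_newick(t_core, file.path(outdir, "tree_core.nwk"))
      } else if (verbose) {
        message(sprintf("[phylogeny] only %d single-copy core clusters (< %d): %s",
                        n_sc, ph$n_clusters, "skipping core-genome tree"))
      }
    }
    list(pan = t_pan, core = t_core)
  })

  screen <- stage("screen", verbose, {
    res <- screen_markers(pm, clustering, gs, config$screen,
                          scoring = config$clustering$scoring)
    write_screen_report(res, file.path(outdir, "screen_report.tsv"))
    res
  })
  marker_seq <- gene_seq(gs, screen$selected$rep_genome_id,
                         screen$selected$rep_gene_id)
  marker_rec <- genome_record(screen$selected$rep_genome_id, "marker",
                              setNames(marker_seq, screen$selected$rep_gene_id))
  write_gene_fasta(marker_rec, file.path(outdir, "marker.fasta"))

  primers <- stage("primers", verbose, {
    pr <- config$primers
    pairs <- design_primers(marker_seq, pr$constraints, n_max = pr$n_max)
    sel <- select_specific_primers(pairs, gs, max_mismatch = pr$max_mismatch,
                                   clamp = pr$clamp,
                                   max_product = pr$max_product)
    write_primer_table(sel$pair, file.path(outdir, "primers.tsv"))
    write_specificity_report(sel$report, file.path(outdir, "specificity.tsv"))
    sel
  })

  qfit <- stage("qpcr", verbose, {
    q <- config$qpcr
    obs <- if (!is.null(q$observations)) read_ct_table(q$observations)
      else simulate_ct(q$true_slope, q$true_intercept, q$log10_concs,
                       q$noise_sd, seed = q$seed)
    write_tsv(obs, file.path(outdir, "qpcr_observations.tsv"))
    fit <- fit_standard_curve(obs)
    write_standard_curve(fit, file.path(outdir, "standard_curve.tsv"))
    fit
  })

  summary <- list(
    n_genomes = length(gs$genomes),
    n_genes = nrow(clustering$members),
    pan_size = part$pan_size,
    n_core = length(part$core),
    n_accessory = length(part$accessory),
    n_unique = length(part$unique),
    n_shared_target = length(screen$shared_in_target),
    n_passed_homology = nrow(screen$ranked),
    selected_marker = screen$selected$cluster_id,
    marker_length_nt = screen$selected$length_nt,
    forward_primer = primers$pair$forward_seq,
    reverse_primer = primers$pair$reverse_seq,
    product_size_bp = primers$pair$product_size,
    specific = primers$report$specific,
    qpcr_slope = qfit$slope,
    qpcr_intercept = qfit$intercept,
    qpcr_r_squared = qfit$r_squared,
    qpcr_efficiency_pct = qfit$efficiency_pct,
    qpcr_high_efficiency = qfit$high_efficiency)
  summary_df <- data.frame(key = names(summary),
                           value = vapply(summary, function(v)
                             format(v, digits = 10), character(1)))
  write_tsv(summary_df, file.path(outdir, "run_summary.tsv"))

  out <- list(summary = summary, genome_set = gs, community = community,
              clustering = clustering, pan_matrix = pm, partition = part,
              trees = trees, screen = screen, primers = primers,
              standard_curve = qfit, outdir = outdir, config = config)
  class(out) <- "run_report"
  out
}

echo_config <- function(config, path) {
  drop_class <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, drop_class)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  yaml::write_yaml(drop_class(unclass(config)), path)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat("panmarker run\n")
  cat(sprintf("  %d genomes, %d genes -> pan %d = core %d + accessory %d + unique %d\n",
              s$n_genomes, s$n_genes, s$pan_size, s$n_core, s$n_accessory,
              s$n_unique))
  cat(sprintf("  screen: %d clade-shared clusters, %d passed homology, selected %s (%d nt)\n",
              s$n_shared_target, s$n_passed_homology, s$selected_marker,
              s$marker_length_nt))
  cat(sprintf("  primers: F %s / R %s, product %d bp, specific: %s\n",
              s$forward_primer, s$reverse_primer, s$product_size_bp,
              if (s$specific) "yes" else "NO"))
  cat(sprintf("  qPCR: slope %.3f, intercept %.3f, R2 %.4f, efficiency %.1f%% (%s)\n",
              s$qpcr_slope, s$qpcr_intercept, s$qpcr_r_squared,
              s$qpcr_efficiency_pct,
              if (s$qpcr_high_efficiency) "high-efficiency" else "not qualified"))
  cat("  artifacts in ", x$outdir, "\n", sep = "")
  invisible(x)
}
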