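# Synthetic bacterial community generator with full ground truth.
#
# The generative model: every shared gene family has an ancestral sequence
# drawn at the target GC; each species carries a species allele obtained by
# per-site substitution at `between_species_divergence`, and each genome a
# genome allele obtained by further substitution at
# `within_species_divergence` (substitution-only by default; an optional
# indel rate stresses the aligner). Core families are present in every
# genome; accessory families in every genome of a random subset of >= 2
# species (patchy presence); singleton genes are fresh unrelated sequences
# private to one genome. Planted marker genes are present in every genome of
# the target species only (alleles diverge from the marker ancestor at the
# within-species rate, so pairwise identities fall in the ~94-100% range at
# the default 0.02), with an optional distant homolog planted in one
# non-target species at a chosen identity (the paper-motivated default is
# 0.36, safely below the 0.50 clustering cutoff).

#' Specification of a synthetic community
#'
#' Defaults emulate a cohort of nine closely related lactic-acid-bacterium
#' species: five genomes of the target species, twenty non-target genomes
#' across eight other species, 120 conserved core families, 80 patchy
#' accessory families, 20 singleton genes and one planted clade-unique
#' marker with a 36%-identity homolog in one non-target species.
#'
#' @param n_species number of species (>= 2, default 9); species labels are
#'   `sp01`, `sp02`, ... with `sp01` the target.
#' @param genomes_per_species integer vector (length `n_species`) of genome
#'   counts; default `c(5, 3, 3, 3, 3, 2, 2, 2, 2)`.
#' @param n_core_genes,n_accessory_genes,n_unique_genes family counts
#'   (defaults 120 / 80 / 20).
#' @param n_planted_markers number of clade-unique marker genes planted in
#'   the target species (default 1).
#' @param gene_length_range min/max gene length in nt (default 250–450).
#' @param marker_length marker gene length in nt (default 1200; long enough
#'   to host a ~130 bp product with flanks and to keep within-clade identity
#'   estimates stable).
#' @param within_species_divergence per-site substitution probability from
#'   the species allele to a genome allele (default 0.02; two genomes of a
#'   species then measure ~96% identity, i.e. the 94–100% regime).
#' @param between_species_divergence per-site substitution probability from
#'   the family ancestor to a species allele (default 0.10; cross-species
#'   identity ~0.81, so shared families stay united at a 0.50 cutoff).
#' @param marker_homolog_identity identity of the distant marker homolog
#'   planted in `marker_homolog_species`, or `NULL` for none (default 0.36).
#'   Values at or above 0.5 would place the homolog inside the marker
#'   cluster at the standard cutoff and must be enabled explicitly with
#'   `allow_high_homolog = TRUE` (used to exercise the screen's exclusion
#'   path).
#' @param marker_homolog_species species label hosting the homolog
#'   (default `sp02`).
#' @param indel_rate per-site insertion/deletion probability applied with
#'   the substitutions (default 0, substitution-only).
#' @param gc_target target GC fraction of generated sequences (default 0.47).
#' @param seed integer seed; the whole community is deterministic per seed.
#' @param allow_high_homolog see `marker_homolog_identity`.
#' @return object of class `community_spec`.
#' @export
community_spec <- function(n_species = 9L,
                           genomes_per_species = c(5L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L),
                           n_core_genes = 120L, n_accessory_genes = 80L,
                           n_unique_genes = 20L, n_planted_markers = 1L,
                           gene_length_range = c(250L, 450L),
                           marker_length = 1200L,
                           within_species_divergence = 0.02,
                           between_species_divergence = 0.10,
                           marker_homolog_identity = 0.36,
                           marker_homolog_species = "sp02",
                           indel_rate = 0, gc_target = 0.47, seed = 1L,
                           allow_high_homolog = FALSE) {
  stopifnot(n_species >= 2L, length(genomes_per_species) == n_species,
            all(genomes_per_species >= 1L),
            n_core_genes >= 0L, n_accessory_genes >= 0L, n_unique_genes >= 0L,
            n_planted_markers >= 1L,
            length(gene_length_range) == 2L,
            gene_length_range[1] >= 50L,
            gene_length_range[1] <= gene_length_range[2],
            marker_length >= 200L,
            within_species_divergence >= 0, within_species_divergence < 1,
            between_species_divergence >= 0, between_species_divergence < 1,
            within_species_divergence <= between_species_divergence,
            indel_rate >= 0, indel_rate < 0.2,
            gc_target > 0, gc_target < 1, !is.null(seed))
  if (!is.null(marker_homolog_identity)) {
    stopifnot(marker_homolog_identity > 0, marker_homolog_identity < 1)
    if (marker_homolog_identity >= 0.5 && !allow_high_homolog)
      stop("marker_homolog_identity >= 0.5 would merge the homolog into the ",
           "marker cluster at the standard cutoff; set allow_high_homolog ",
           "= TRUE if this is intended", call. = FALSE)
    species <- sprintf("sp%02d", seq_len(n_species))
    if (!marker_homolog_species %in% species[-1])
      stop("marker_homolog_species must be a non-target species label",
           call. = FALSE)
  }
  out <- list(n_species = as.integer(n_species),
              genomes_per_species = as.integer(genomes_per_species),
              n_core_genes = as.integer(n_core_genes),
              n_accessory_genes = as.integer(n_accessory_genes),
              n_unique_genes = as.integer(n_unique_genes),
              n_planted_markers = as.integer(n_planted_markers),
              gene_length_range = as.integer(gene_length_range),
              marker_length = as.integer(marker_length),
              within_species_divergence = within_species_divergence,
              between_species_divergence = between_species_divergence,
              marker_homolog_identity = marker_homolog_identity,
              marker_homolog_species = marker_homolog_species,
              indel_rate = indel_rate, gc_target = gc_target,
              seed = as.integer(seed))
  class(out) <- "community_spec"
  out
}

BASES <- c("A", "C", "G", "T")

random_seq_chars <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(BASES, n, replace = TRUE, prob = p)
}

# substitute each site with probability p_sub (uniform over the 3 other
# bases, via a random cyclic offset); optionally apply indels at indel_rate
# (half deletions, half single-base insertions)
mutate_chars <- function(chars, p_sub, indel_rate = 0, gc = 0.5) {
  hit <- which(runif(length(chars)) < p_sub)
  if (length(hit)) {
    off <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- BASES[(match(chars[hit], BASES) - 1L + off) %% 4L + 1L]
  }
  if (indel_rate > 0) {
    r <- runif(length(chars))
    del <- r < indel_rate / 2
    ins <- r >= indel_rate / 2 & r < indel_rate
    out <- vector("list", length(chars))
    for (i in seq_along(chars)) {
      if (del[i]) next
      out[[i]] <- if (ins[i]) c(chars[i], random_seq_chars(1L, gc)) else chars[i]
    }
    chars <- unlist(out)
  }
  chars
}

#' Expected pairwise identity after independent divergence
#'
#' Per-site collision model for two sequences independently diverged from a
#' common ancestor, each site substituted with probability `d` (uniform over
#' the three other bases): a site matches if both lineages kept it,
#' `(1 - d)^2`, or both substituted it to the same base, `d^2 / 3`. Used to
#' calibrate community parameters against measured identities; the aligner's
#' measured identity sits slightly above this value for highly diverged
#' pairs because score-optimal alignments may gap around mismatch runs.
#'
#' @param divergence per-lineage substitution probability in `[0, 1)`.
#' @return expected identity in `[0, 1]`.
#' @examples
#' expected_identity(0)     # 1
#' expected_identity(0.02)  # ~0.96
#' @export
expected_identity <- function(divergence) {
  stopifnot(all(divergence >= 0), all(divergence < 1))
  (1 - divergence)^2 + divergence^2 / 3
}

#' Generate a synthetic community with ground truth
#'
#' @param spec a [community_spec()].
#' @return object of class `community`: list with
#'   \describe{
#'     \item{genome_set}{a [genome_set()] (target species `sp01`).}
#'     \item{truth}{ground truth: `families` (data.frame `genome_id`,
#'       `gene_id`, `family`), `family_class` (data.frame `family`,
#'       `class` in core/accessory/unique/clade_specific/marker_homolog),
#'       `marker_families`, `species_tree` (Newick star over species),
#'       `spec` (the generating spec).}
#'   }
#' @export
generate_community <- function(spec = community_spec()) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(spec$seed, generate_community_impl(spec))
}

generate_community_impl <- function(spec) {
  species <- sprintf("sp%02d", seq_len(spec$n_species))
  target <- species[1]
  genome_ids <- unlist(lapply(seq_len(spec$n_species), function(i)
    sprintf("%s_g%02d", species[i], seq_len(spec$genomes_per_species[i]))))
  genome_species <- rep(species, spec$genomes_per_species)
  names(genome_species) <- genome_ids

  glen <- function() sample(seq(spec$gene_length_range[1],
                                spec$gene_length_range[2]), 1L)
  genes <- setNames(vector("list", length(genome_ids)), genome_ids)
  t_genome <- character(0); t_family <- character(0)
  add_gene <- function(genome, family, chars) {
    genes[[genome]][[family]] <<- paste(chars, collapse = "")
    t_genome[[length(t_genome) + 1L]] <<- genome
    t_family[[length(t_family) + 1L]] <<- family
  }

  f_family <- character(0); f_class <- character(0)
  note_family <- function(family, class) {
    f_family[[length(f_family) + 1L]] <<- family
    f_class[[length(f_class) + 1L]] <<- class
  }

  emit_family <- function(family, class, members_species) {
    anc <- random_seq_chars(glen(), spec$gc_target)
    note_family(family, class)
    for (sp in members_species) {
      sp_allele <- mutate_chars(anc, spec$between_species_divergence,
                                spec$indel_rate, spec$gc_target)
      for (g in genome_ids[genome_species == sp]) {
        add_gene(g, family,
                 mutate_chars(sp_allele, spec$within_species_divergence,
                              spec$indel_rate, spec$gc_target))
      }
    }
  }

  for (i in seq_len(spec$n_core_genes))
    emit_family(sprintf("core%04d", i), "core", species)
  for (i in seq_len(spec$n_accessory_genes)) {
    # patchy presence over a proper species subset; a subset equal to the
    # target clade alone would be indistinguishable from a planted marker,
    # so single-species subsets are drawn from the non-target species
    k <- sample(seq_len(max(1L, spec$n_species - 1L)), 1L)
    sub <- if (k == 1L) sample(species[-1], 1L) else sort(sample(species, k))
    emit_family(sprintf("acc%04d", i), "accessory", sub)
  }
  if (spec$n_unique_genes > 0L) {
    hosts <- sample(genome_ids, spec$n_unique_genes, replace = TRUE)
    for (i in seq_len(spec$n_unique_genes)) {
      fam <- sprintf("uniq%04d", i)
      note_family(fam, "unique")
      add_gene(hosts[i], fam, random_seq_chars(glen(), spec$gc_target))
    }
  }

  marker_fams <- sprintf("marker%02d", seq_len(spec$n_planted_markers))
  target_genomes <- genome_ids[genome_species == target]
  for (m in seq_len(spec$n_planted_markers)) {
    anc <- random_seq_chars(spec$marker_length, spec$gc_target)
    note_family(marker_fams[m], "clade_specific")
    for (g in target_genomes)
      add_gene(g, marker_fams[m],
               mutate_chars(anc, spec$within_species_divergence,
                            spec$indel_rate, spec$gc_target))
    if (m == 1L && !is.null(spec$marker_homolog_identity)) {
      hom <- mutate_chars(anc, 1 - spec$marker_homolog_identity)
      fam <- "marker_homolog"
      note_family(fam, "marker_homolog")
      for (g in genome_ids[genome_species == spec$marker_homolog_species])
        add_gene(g, fam,
                 mutate_chars(hom, spec$within_species_divergence,
                              spec$indel_rate, spec$gc_target))
    }
  }

  records <- lapply(genome_ids, function(g)
    genome_record(g, genome_species[[g]], unlist(genes[[g]])))
  gs <- genome_set(records, target)
  newick <- paste0("(", paste0(species, ":1", collapse = ","), ");")
  out <- list(
    genome_set = gs,
    truth = list(families = data.frame(genome_id = t_genome,
                                       gene_id = t_family, family = t_family,
                                       stringsAsFactors = FALSE),
                 family_class = data.frame(family = f_family, class = f_class,
                                           stringsAsFactors = FALSE),
                 marker_families = marker_fams,
                 species_tree = newick,
                 spec = spec))
  class(out) <- "community"
  out
}

#' @export
print.community <- function(x, ...) {
  sp <- x$truth$spec
  cat(sprintf(paste0("<community> %d genomes / %d species (target sp01: %d ",
                     "genomes); %d gene families, %d planted marker(s)\n"),
              length(x$genome_set$genomes), sp$n_species,
              sp$genomes_per_species[1], nrow(x$truth$family_class),
              sp$n_planted_markers))
  invisible(x)
}

#' Write a community to disk in pipeline-readable form
#'
#' One gene FASTA per genome plus `species.tsv`, and the ground truth as
#' TSVs + Newick under `truth/`.
#'
#' @param community a [generate_community()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "community"))
  dir.create(file.path(dir, "genomes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  gs <- community$genome_set
  for (g in gs$genomes)
    write_gene_fasta(g, file.path(dir, "genomes", paste0(g$genome_id, ".fasta")))
  labs <- data.frame(genome_id = names(gs$genomes),
                     species_label = unname(species_labels(gs)))
  write_tsv(labs, file.path(dir, "species.tsv"))
  write_tsv(community$truth$families, file.path(dir, "truth", "families.tsv"))
  write_tsv(community$truth$family_class,
            file.path(dir, "truth", "family_class.tsv"))
  writeLines(community$truth$species_tree,
             file.path(dir, "truth", "species_tree.nwk"))
  invisible(dir)
}
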