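# Genome ingest: gene multi-FASTA, optional genome FASTA + GFF3 CDS
# extraction, species label table, and the containers the pipeline works on.
#
# Internal conventions: sequences upper-case over {A,C,G,T,N} (U mapped to T
# at ingest, other ambiguity codes rejected); species labels are free strings
# matched exactly (case-sensitive).

VALID_SEQ_RE <- "^[ACGTN]+$"

normalize_seq <- function(seq) {
  chartr("U", "T", toupper(seq))
}

#' Construct a genome record
#'
#' One annotated genome: an identifier, a species label, and its gene (CDS)
#' nucleotide sequences. Sequences are upper-cased and `U` is mapped to `T`;
#' characters outside `A`,`C`,`G`,`T`,`N` are rejected.
#'
#' @param genome_id single non-empty string, unique within a [genome_set()].
#' @param species_label single non-empty string; matched exactly
#'   (case-sensitive) against `target_species`.
#' @param genes named character vector of gene sequences; names are gene ids,
#'   unique within the genome, order preserved.
#' @param coords optional data.frame of source coordinates
#'   (`gene_id`, `contig_id`, `start`, `end`, `strand`).
#' @return an object of class `genome_record` with elements `genome_id`,
#'   `species_label`, `genes`, `gc_fraction` (GC over all genes, `N` excluded
#'   from numerator and denominator) and optionally `coords`.
#' @seealso [read_gene_fasta()], [extract_cds_from_gff()], [genome_set()]
#' @export
genome_record <- function(genome_id, species_label, genes, coords = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id),
            is.character(species_label), length(species_label) == 1L,
            nzchar(species_label), is.character(genes), length(genes) >= 1L)
  ids <- names(genes)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every gene needs a non-empty gene_id (names of `genes`)", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene_id in genome '", genome_id, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  genes <- vapply(genes, normalize_seq, character(1))
  names(genes) <- ids
  if (any(!nzchar(genes)))
    stop("empty gene sequence in genome '", genome_id, "'", call. = FALSE)
  bad <- ids[!grepl(VALID_SEQ_RE, genes)]
  if (length(bad))
    stop("invalid characters (only A/C/G/T/N/U allowed) in genes: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  out <- list(genome_id = genome_id, species_label = species_label,
              genes = genes, gc_fraction = compute_gc(paste(genes, collapse = "")),
              coords = coords)
  class(out) <- "genome_record"
  out
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s  [%s]\n  %d genes, %.1f kb, GC %.1f%%\n",
              x$genome_id, x$species_label, length(x$genes),
              sum(nchar(x$genes)) / 1000, 100 * x$gc_fraction))
  invisible(x)
}

#' Construct a genome set
#'
#' The collection of genomes a discovery run operates on, together with the
#' target species whose clade-unique marker is sought. At least one genome
#' must carry the target label and at least one must not.
#'
#' @param genomes list of [genome_record()] objects with unique `genome_id`s.
#' @param target_species single string, the species label to screen for.
#' @return object of class `genome_set`: a list with `genomes` (named by
#'   genome id) and `target_species`.
#' @export
genome_set <- function(genomes, target_species) {
  stopifnot(is.list(genomes), length(genomes) >= 2L,
            is.character(target_species), length(target_species) == 1L,
            nzchar(target_species))
  ok <- vapply(genomes, inherits, logical(1), "genome_record")
  if (!all(ok)) stop("`genomes` must be a list of genome_record objects", call. = FALSE)
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate genome_id: ", paste(dup, collapse = ", "), call. = FALSE)
  labs <- vapply(genomes, `[[`, character(1), "species_label")
  if (!any(labs == target_species))
    stop("no genome carries species_label '", target_species, "'", call. = FALSE)
  if (all(labs == target_species))
    stop("all genomes carry the target label; need at least one non-target genome",
         call. = FALSE)
  names(genomes) <- ids
  out <- list(genomes = genomes, target_species = target_species)
  class(out) <- "genome_set"
  out
}

#' @export
print.genome_set <- function(x, ...) {
  labs <- species_labels(x)
  cat(sprintf("<genome_set> %d genomes, %d species; target '%s' (%d genomes)\n",
              length(x$genomes), length(unique(labs)), x$target_species,
              sum(labs == x$target_species)))
  invisible(x)
}

species_labels <- function(genome_set) {
  vapply(genome_set$genomes, `[[`, character(1), "species_label")
}

target_genome_ids <- function(genome_set) {
  names(genome_set$genomes)[species_labels(genome_set) == genome_set$target_species]
}

#' GC fraction of nucleotide sequences
#'
#' `(G + C) / (A + C + G + T)`; `N` is excluded from both numerator and
#' denominator. Invariant under reverse complement.
#'
#' @param seq character vector of nucleotide sequences (case-insensitive).
#' @return numeric vector of fractions in `[0, 1]`.
#' @examples
#' compute_gc("GGCC")                  # 1
#' compute_gc("CATGGCCGATATGCAGCATT")  # 0.50
#' @export
compute_gc <- function(seq) {
  stopifnot(is.character(seq), all(nzchar(seq)))
  vapply(seq, function(s) {
    s <- normalize_seq(s)
    n <- nchar(s)
    gc <- n - nchar(gsub("[GC]", "", s))
    at <- n - nchar(gsub("[AT]", "", s))
    if (gc + at == 0L)
      stop("GC content undefined: sequence has no unambiguous base", call. = FALSE)
    gc / (gc + at)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a gene multi-FASTA as a genome record
#'
#' Each FASTA record becomes one gene; the header token before the first
#' whitespace is the gene id. Wrapped and single-line FASTA are equivalent.
#'
#' @param path path to a FASTA file with at least one record.
#' @param genome_id,species_label identifiers for the resulting record.
#' @return a [genome_record()].
#' @export
read_gene_fasta <- function(path, genome_id, species_label) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("not readable as FASTA: ", path,
                                           " (", conditionMessage(e), ")", call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  genes <- as.character(set)
  names(genes) <- ids
  genome_record(genome_id, species_label, genes)
}

#' Write a genome record as gene multi-FASTA
#'
#' Round-trips exactly with [read_gene_fasta()]: gene ids, order and
#' sequences are preserved.
#'
#' @param genome a [genome_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_record"))
  set <- Biostrings::BStringSet(genome$genes)
  Biostrings::writeXStringSet(set, path, format = "fasta", width = 70L)
  invisible(path)
}

#' Extract CDS sequences from a genome FASTA plus GFF3
#'
#' Reads GFF3 `CDS` features (1-based inclusive coordinates), cuts them out of
#' the genome contigs, reverse-complements minus-strand features, and takes
#' the gene id from the `ID` attribute.
#'
#' @param genome_fasta path to the genome (contig) FASTA.
#' @param gff_path path to the GFF3 annotation.
#' @param genome_id,species_label identifiers for the resulting record.
#' @return a [genome_record()] with a `coords` table.
#' @export
extract_cds_from_gff <- function(genome_fasta, gff_path, genome_id, species_label) {
  contigs <- Biostrings::readBStringSet(genome_fasta, format = "fasta")
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gff <- rtracklayer::import(gff_path, format = "gff3")
  gff <- gff[gff$type == "CDS"]
  if (length(gff) == 0L) stop("no CDS features in ", gff_path, call. = FALSE)
  contig_id <- as.character(GenomicRanges::seqnames(gff))
  starts <- GenomicRanges::start(gff)
  ends <- GenomicRanges::end(gff)
  strands <- as.character(GenomicRanges::strand(gff))
  ids <- gff$ID
  if (is.null(ids) || any(is.na(ids)))
    stop("every CDS needs an ID attribute", call. = FALSE)
  missing <- setdiff(unique(contig_id), names(contigs))
  if (length(missing))
    stop("contigs in GFF absent from FASTA: ", paste(missing, collapse = ", "),
         call. = FALSE)
  lens <- setNames(nchar(as.character(contigs)), names(contigs))
  over <- ends > lens[contig_id] | starts < 1L
  if (any(over))
    stop("CDS coordinates exceed contig length for: ",
         paste(ids[over], collapse = ", "), call. = FALSE)
  seqs <- substr(as.character(contigs)[contig_id], starts, ends)
  minus <- strands == "-"
  seqs[minus] <- reverse_complement(seqs[minus])
  names(seqs) <- ids
  coords <- data.frame(gene_id = ids, contig_id = contig_id, start = starts,
                       end = ends, strand = strands, stringsAsFactors = FALSE)
  genome_record(genome_id, species_label, seqs, coords = coords)
}

#' Read a species-label table
#'
#' Two-column TSV mapping `genome_id` to `species_label`; labels are used
#' verbatim (no case folding).
#'
#' @param path path to the TSV (header optional: detected by the literal
#'   first-line `genome_id<TAB>species_label`).
#' @return data.frame with columns `genome_id`, `species_label`.
#' @export
read_species_table <- function(path) {
  first <- readLines(path, n = 1L)
  header <- identical(strsplit(first, "\t", fixed = TRUE)[[1]][1:2],
                      c("genome_id", "species_label"))
  df <- read.delim(path, sep = "\t", header = header, stringsAsFactors = FALSE)
  if (!header) names(df)[1:2] <- c("genome_id", "species_label")
  df <- df[, c("genome_id", "species_label")]
  if (anyDuplicated(df$genome_id))
    stop("duplicate genome_id in species table", call. = FALSE)
  df
}

#' Read a directory of gene FASTAs plus a species table as a genome set
#'
#' @param fasta_paths named character vector of per-genome gene FASTA paths;
#'   names are genome ids (defaults to file base names without extension).
#' @param species_table data.frame from [read_species_table()] (or a path).
#' @param target_species species label to screen for.
#' @return a [genome_set()].
#' @export
read_genome_set <- function(fasta_paths, species_table, target_species) {
  if (is.character(species_table)) species_table <- read_species_table(species_table)
  if (is.null(names(fasta_paths)))
    names(fasta_paths) <- sub("\\.(fa|fna|fasta)$", "", basename(fasta_paths))
  lab <- setNames(species_table$species_label, species_table$genome_id)
  missing <- setdiff(names(fasta_paths), names(lab))
  if (length(missing))
    stop("genomes missing from species table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  genomes <- lapply(names(fasta_paths), function(g)
    read_gene_fasta(fasta_paths[[g]], g, lab[[g]]))
  genome_set(genomes, target_species)
}
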