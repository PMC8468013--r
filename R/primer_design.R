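# Primer design inside the selected marker gene, and in-silico PCR
# validation of a primer pair against every genome of the set.
#
# Position convention in this file: 1-based inclusive coordinates on the
# marker/template plus strand. A primer pair is (forward primer = plus-strand
# window read 5'->3'; reverse primer = reverse complement of a downstream
# plus-strand window, i.e. the sequence as synthesized). Product size is the
# inclusive span between the two primers' 5' ends — for two 20-mers around an
# 88 nt insert that is 20 + 88 + 20 = 128 bp.

#' Primer design constraints
#'
#' @param primer_length allowed primer lengths in nt (default 18–24).
#' @param gc allowed primer GC fraction (default `[0.40, 0.60]`).
#' @param tm allowed primer melting temperature in °C by the Wallace rule
#'   (default `[55, 65]`).
#' @param max_homopolymer longest allowed single-base run (default 4; a run
#'   of 5 or more rejects the primer).
#' @param product_size allowed product size in bp (default `[80, 200]`).
#' @param product_opt product size whose closeness breaks ties in ranking
#'   (default 130 bp).
#' @param max_dtm maximum |Tm difference| within a pair in °C (default 3).
#' @return object of class `primer_constraints`.
#' @export
primer_constraints <- function(primer_length = c(18L, 24L), gc = c(0.40, 0.60),
                               tm = c(55, 65), max_homopolymer = 4L,
                               product_size = c(80L, 200L), product_opt = 130L,
                               max_dtm = 3) {
  stopifnot(length(primer_length) == 2L, primer_length[1] <= primer_length[2],
            primer_length[1] >= 10L,
            length(gc) == 2L, length(tm) == 2L, length(product_size) == 2L,
            product_size[1] <= product_size[2], max_homopolymer >= 1L,
            max_dtm >= 0)
  if (gc[1] > gc[2]) stop("impossible constraints: empty GC interval", call. = FALSE)
  if (tm[1] > tm[2]) stop("impossible constraints: empty Tm interval", call. = FALSE)
  out <- list(primer_length = as.integer(primer_length), gc = gc, tm = tm,
              max_homopolymer = as.integer(max_homopolymer),
              product_size = as.integer(product_size),
              product_opt = as.integer(product_opt), max_dtm = max_dtm)
  class(out) <- "primer_constraints"
  out
}

#' Primer melting temperature by the Wallace rule
#'
#' `Tm = 2 * (A + T) + 4 * (G + C)` °C; the standard quick estimate for
#' oligos up to ~30 nt.
#'
#' @param primer_seq nucleotide string over A/C/G/T, length <= 30.
#' @return Tm in °C.
#' @examples
#' wallace_tm("CATGGCCGATATGCAGCATT")  # 60
#' @export
wallace_tm <- function(primer_seq) {
  stopifnot(is.character(primer_seq), length(primer_seq) == 1L)
  s <- normalize_seq(primer_seq)
  if (nchar(s) > 30L) stop("Wallace rule only valid up to 30 nt", call. = FALSE)
  if (!grepl("^[ACGT]+$", s))
    stop("primer sequence must be unambiguous A/C/G/T", call. = FALSE)
  n <- nchar(s)
  gc <- n - nchar(gsub("[GC]", "", s))
  2 * (n - gc) + 4 * gc
}

#' Predicted product melting temperature
#'
#' Salt-adjusted empirical duplex formula
#' `Tm = 81.5 + 0.41 * GC% - 675 / N + 16.6 * log10([Na+])`, valid for
#' products of at least 50 bp; reported to the nearest 0.5 °C. The predicted
#' value is descriptive only — it is never used as a pass/fail criterion.
#'
#' @param product_seq product nucleotide sequence (N >= 50).
#' @param na_conc monovalent cation concentration in mol/L (default 0.05).
#' @param round round to the nearest 0.5 °C (default TRUE).
#' @return Tm in °C.
#' @export
product_tm <- function(product_seq, na_conc = 0.05, round = TRUE) {
  stopifnot(is.character(product_seq), length(product_seq) == 1L, na_conc > 0)
  n <- nchar(product_seq)
  if (n < 50L) stop("product Tm formula invalid below 50 bp", call. = FALSE)
  gc_pct <- 100 * compute_gc(product_seq)
  tm <- 81.5 + 0.41 * gc_pct - 675 / n + 16.6 * log10(na_conc)
  if (round) round(tm * 2) / 2 else tm
}

has_homopolymer <- function(seq, max_run) {
  grepl(sprintf("([ACGT])\\1{%d,}", max_run), seq)
}

# primer-level checks; returns TRUE/FALSE
primer_ok <- function(seq, cn) {
  n <- nchar(seq)
  if (n < cn$primer_length[1] || n > cn$primer_length[2]) return(FALSE)
  if (has_homopolymer(seq, cn$max_homopolymer)) return(FALSE)
  gc <- compute_gc(seq)
  if (gc < cn$gc[1] || gc > cn$gc[2]) return(FALSE)
  tm <- wallace_tm(seq)
  tm >= cn$tm[1] && tm <= cn$tm[2]
}

gc_clamped <- function(seq) substr(seq, nchar(seq), nchar(seq)) %in% c("G", "C")

# enumerate all primer-level windows: data.frame(start, end, seq, tm, gc)
# (vectorised per window length; the Wallace Tm of an ACGT 18-24-mer is
# 2*(A+T) + 4*(G+C), so GC and Tm come from one character count)
enumerate_windows <- function(marker_seq, cn, reverse) {
  L <- nchar(marker_seq)
  rows <- list(); idx <- 0L
  for (len in seq(cn$primer_length[1], cn$primer_length[2])) {
    if (len > L) next
    starts <- seq_len(L - len + 1L)
    win <- substring(marker_seq, starts, starts + len - 1L)
    p <- if (reverse) reverse_complement(win) else win
    keep <- grepl("^[ACGT]+$", p) &
      !grepl(sprintf("([ACGT])\\1{%d,}", cn$max_homopolymer), p)
    if (!any(keep)) next
    ngc <- len - nchar(gsub("[GC]", "", p))
    gc <- ngc / len
    tm <- 2 * (len - ngc) + 4 * ngc
    keep <- keep & gc >= cn$gc[1] & gc <= cn$gc[2] &
      tm >= cn$tm[1] & tm <= cn$tm[2]
    if (!any(keep)) next
    idx <- idx + 1L
    rows[[idx]] <- data.frame(start = starts[keep], end = starts[keep] + len - 1L,
                              seq = p[keep], tm = tm[keep], gc = gc[keep],
                              stringsAsFactors = FALSE)
  }
  if (idx == 0L) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, method = "radix"), ]
}

#' Design candidate primer pairs inside a marker sequence
#'
#' Exhaustively enumerates forward/reverse primer windows satisfying the
#' primer-level constraints (length, GC, Wallace Tm, homopolymer run), pairs
#' them under the product-size and |dTm| constraints, and ranks pairs by
#' |dTm|, then closeness of the product size to `product_opt`, then a
#' preference for G/C 3' ends, with deterministic positional tie-breaks.
#'
#' @param marker_seq the marker gene sequence (plus strand).
#' @param constraints a [primer_constraints()].
#' @param n_max maximum number of pairs returned (default 100).
#' @return object of class `primer_set`: data.frame with one row per pair:
#'   `forward_seq`, `reverse_seq` (5'->3' as synthesized), positions
#'   (`fw_start`, `fw_end`, `rv_start`, `rv_end` on the marker), per-primer
#'   `gc`/`tm`, `product_size`, `dtm`, best first.
#' @export
design_primers <- function(marker_seq, constraints = primer_constraints(),
                           n_max = 100L) {
  stopifnot(is.character(marker_seq), length(marker_seq) == 1L)
  cn <- constraints
  marker_seq <- normalize_seq(marker_seq)
  L <- nchar(marker_seq)
  if (L < cn$product_size[1])
    stop("marker (", L, " nt) shorter than the minimum product size", call. = FALSE)
  fw <- enumerate_windows(marker_seq, cn, reverse = FALSE)
  rv <- enumerate_windows(marker_seq, cn, reverse = TRUE)
  if (is.null(fw))
    stop("no forward primer window satisfies the primer-level constraints ",
         "(length/GC/Tm/homopolymer)", call. = FALSE)
  if (is.null(rv))
    stop("no reverse primer window satisfies the primer-level constraints ",
         "(length/GC/Tm/homopolymer)", call. = FALSE)
  fi <- list(); ri <- list(); idx <- 0L
  for (i in seq_len(nrow(fw))) {
    # product spans fw 5' (fw$start) to rv 5' (rv$end): size = rv_end - fw_start + 1
    size <- rv$end - fw$start[i] + 1L
    j <- which(size >= cn$product_size[1] & size <= cn$product_size[2] &
                 rv$start > fw$end[i] &  # sites must not overlap, 3' ends facing
                 abs(rv$tm - fw$tm[i]) <= cn$max_dtm)
    if (!length(j)) next
    idx <- idx + 1L
    fi[[idx]] <- rep.int(i, length(j)); ri[[idx]] <- j
  }
  if (idx == 0L)
    stop("no primer pair satisfies the pairing constraints ",
         "(product size in [", cn$product_size[1], ", ", cn$product_size[2],
         "] bp and |dTm| <= ", cn$max_dtm, ")", call. = FALSE)
  fi <- unlist(fi); ri <- unlist(ri)
  res <- data.frame(
    forward_seq = fw$seq[fi], reverse_seq = rv$seq[ri],
    fw_start = fw$start[fi], fw_end = fw$end[fi],
    rv_start = rv$start[ri], rv_end = rv$end[ri],
    fw_gc = fw$gc[fi], rv_gc = rv$gc[ri],
    fw_tm = fw$tm[fi], rv_tm = rv$tm[ri],
    product_size = rv$end[ri] - fw$start[fi] + 1L,
    dtm = abs(rv$tm[ri] - fw$tm[fi]), stringsAsFactors = FALSE)
  clamp <- gc_clamped(res$forward_seq) + gc_clamped(res$reverse_seq)
  ord <- order(res$dtm, abs(res$product_size - cn$product_opt), -clamp,
               res$fw_start, res$fw_end, res$rv_end, method = "radix")
  res <- head(res[ord, ], n_max)
  rownames(res) <- NULL
  class(res) <- c("primer_set", "data.frame")
  res
}

#' @export
print.primer_set <- function(x, ...) {
  cat(sprintf("<primer_set> %d candidate pair(s); best:\n", nrow(x)))
  b <- x[1L, ]
  cat(sprintf("  F 5'-%s-3' (Tm %.0f, GC %.2f)\n  R 5'-%s-3' (Tm %.0f, GC %.2f)\n",
              b$forward_seq, b$fw_tm, b$fw_gc, b$reverse_seq, b$rv_tm, b$rv_gc))
  cat(sprintf("  product %d bp at %d..%d\n", b$product_size, b$fw_start, b$rv_end))
  invisible(x)
}

#' Construct a primer pair by hand
#'
#' @param forward_seq,reverse_seq primer sequences 5'->3' as synthesized
#'   (the reverse primer is the reverse complement of the template's plus
#'   strand).
#' @param product_size intended product size in bp, if known.
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(forward_seq, reverse_seq, product_size = NA_integer_) {
  forward_seq <- normalize_seq(forward_seq)
  reverse_seq <- normalize_seq(reverse_seq)
  stopifnot(grepl("^[ACGT]+$", forward_seq), grepl("^[ACGT]+$", reverse_seq))
  out <- list(forward_seq = forward_seq, reverse_seq = reverse_seq,
              forward_tm = wallace_tm(forward_seq),
              reverse_tm = wallace_tm(reverse_seq),
              forward_gc = compute_gc(forward_seq),
              reverse_gc = compute_gc(reverse_seq),
              product_size = as.integer(product_size))
  class(out) <- "primer_pair"
  out
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair>\n  F 5'-%s-3' (%d nt, Tm %.0f, GC %.2f)\n",
              x$forward_seq, nchar(x$forward_seq), x$forward_tm, x$forward_gc))
  cat(sprintf("  R 5'-%s-3' (%d nt, Tm %.0f, GC %.2f)\n",
              x$reverse_seq, nchar(x$reverse_seq), x$reverse_tm, x$reverse_gc))
  if (!is.na(x$product_size))
    cat(sprintf("  intended product %d bp\n", x$product_size))
  invisible(x)
}

as_primer_pair <- function(x) {
  if (inherits(x, "primer_pair")) return(x)
  if (inherits(x, "primer_set") || is.data.frame(x))
    return(primer_pair(x$forward_seq[1L], x$reverse_seq[1L], x$product_size[1L]))
  stop("cannot interpret as primer pair", call. = FALSE)
}

# Precompute the four scan patterns of a primer pair.
# plus sites: primer occurs verbatim (extension rightward), 3' clamp at the
# pattern's right end; minus sites: reverse complement of the primer occurs
# (extension leftward), 3' clamp at the pattern's left end.
prep_scan <- function(pp, max_mismatch, clamp) {
  mk <- function(role, strand, pattern, exact) {
    list(role = role, strand = strand, pattern = pattern, exact = exact,
         len = nchar(pattern), max_mm = max_mismatch)
  }
  specs <- list()
  for (role in c("F", "R")) {
    p <- if (role == "F") pp$forward_seq else pp$reverse_seq
    n <- nchar(p); cl <- min(clamp, n)
    specs[[paste0(role, "+")]] <- mk(role, "+", p, seq(n - cl + 1L, n))
    specs[[paste0(role, "-")]] <- mk(role, "-", reverse_complement(p), seq_len(cl))
  }
  specs
}

# all binding sites of both primers on one template sequence, given
# precomputed scan specs; NULL when the sequence has none
primer_sites <- function(seq, specs) {
  out <- list(); idx <- 0L
  for (sp in specs) {
    hit <- .primer_scan_cpp(seq, sp$pattern, sp$max_mm, sp$exact)
    if (length(hit$start)) {
      idx <- idx + 1L
      out[[idx]] <- data.frame(role = sp$role, strand = sp$strand,
                               start = hit$start,
                               end = hit$start + sp$len - 1L,
                               mismatches = hit$mismatches,
                               stringsAsFactors = FALSE)
    }
  }
  if (idx == 0L) return(NULL)
  do.call(rbind, out)
}

#' In-silico PCR of a primer pair against a genome set
#'
#' Scans every gene sequence (both strands) of every genome for primer
#' binding sites with at most `max_mismatch` mismatches per primer, the
#' 3'-terminal `clamp` bases required exact (indels are not modelled). Every
#' opposite-strand, inward-facing site pair on the same sequence with product
#' length at most `max_product` is reported as a predicted amplicon; a genome
#' is "amplified" iff it has at least one.
#'
#' @param pair a [primer_pair()] or the best row of a [design_primers()]
#'   result.
#' @param genome_set a [genome_set()].
#' @param max_mismatch mismatch tolerance per primer (default 2).
#' @param clamp number of 3'-terminal bases required exact (default 3).
#' @param max_product maximum product length in bp (default 3000).
#' @return object of class `specificity_report`: list with
#'   \describe{
#'     \item{hits}{data.frame of predicted amplicons: genome, gene, the two
#'       sites with roles and mismatch counts, `product_size`, `product_gc`,
#'       `product_tm` (NA under 50 bp).}
#'     \item{verdicts}{data.frame `genome_id`, `species_label`, `amplified`.}
#'     \item{specific}{`TRUE` iff all target genomes amplify and no
#'       non-target genome does.}
#'   }
#' @export
insilico_pcr <- function(pair, genome_set, max_mismatch = 2L, clamp = 3L,
                         max_product = 3000L) {
  stopifnot(inherits(genome_set, "genome_set"))
  pp <- as_primer_pair(pair)
  specs <- prep_scan(pp, max_mismatch, clamp)
  hits <- list(); idx <- 0L
  for (g in genome_set$genomes) {
    for (gene in names(g$genes)) {
      sites <- primer_sites(g$genes[[gene]], specs)
      if (is.null(sites)) next
      plus <- sites[sites$strand == "+", , drop = FALSE]
      minus <- sites[sites$strand == "-", , drop = FALSE]
      if (nrow(plus) == 0L || nrow(minus) == 0L) next
      for (i in seq_len(nrow(plus))) for (j in seq_len(nrow(minus))) {
        if (minus$start[j] <= plus$end[i]) next          # not inward-facing
        size <- minus$end[j] - plus$start[i] + 1L
        if (size > max_product) next
        prod <- substr(g$genes[[gene]], plus$start[i], minus$end[j])
        idx <- idx + 1L
        hits[[idx]] <- data.frame(
          genome_id = g$genome_id, gene_id = gene,
          fw_role = plus$role[i], fw_start = plus$start[i],
          fw_mismatches = plus$mismatches[i],
          rv_role = minus$role[j], rv_end = minus$end[j],
          rv_mismatches = minus$mismatches[j],
          product_size = size, product_gc = compute_gc(prod),
          product_tm = if (size >= 50L) product_tm(prod) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (idx) do.call(rbind, hits) else
    data.frame(genome_id = character(0), gene_id = character(0),
               fw_role = character(0), fw_start = integer(0),
               fw_mismatches = integer(0), rv_role = character(0),
               rv_end = integer(0), rv_mismatches = integer(0),
               product_size = integer(0), product_gc = numeric(0),
               product_tm = numeric(0))
  labs <- species_labels(genome_set)
  verdicts <- data.frame(genome_id = names(genome_set$genomes),
                         species_label = unname(labs),
                         amplified = names(genome_set$genomes) %in% hits$genome_id,
                         stringsAsFactors = FALSE)
  is_target <- verdicts$species_label == genome_set$target_species
  specific <- all(verdicts$amplified[is_target]) && !any(verdicts$amplified[!is_target])
  out <- list(hits = hits, verdicts = verdicts, specific = specific,
              pair = pp, target_species = genome_set$target_species)
  class(out) <- "specificity_report"
  out
}

#' @export
print.specificity_report <- function(x, ...) {
  v <- x$verdicts
  tgt <- v$species_label == x$target_species
  cat(sprintf(paste0("<specificity_report> target '%s': %d/%d target and ",
                     "%d/%d non-target genomes amplified -> %s\n"),
              x$target_species, sum(v$amplified[tgt]), sum(tgt),
              sum(v$amplified[!tgt]), sum(!tgt),
              if (x$specific) "SPECIFIC" else "not specific"))
  invisible(x)
}

#' Select the first candidate pair that is specific in silico
#'
#' Walks the ranked candidate pairs, keeps those that amplify every target
#' genome (checked on the target subset first, then against the full set),
#' and returns the first fully specific pair with its report.
#'
#' @param pairs a [design_primers()] result.
#' @param genome_set a [genome_set()].
#' @inheritParams insilico_pcr
#' @return list with `pair` (class `primer_pair`), `report`
#'   (class `specificity_report`) and `rank` (row index of the chosen pair).
#' @export
select_specific_primers <- function(pairs, genome_set, max_mismatch = 2L,
                                    clamp = 3L, max_product = 3000L) {
  stopifnot(inherits(pairs, "primer_set"), inherits(genome_set, "genome_set"))
  labs <- species_labels(genome_set)
  targets <- genome_set$genomes[labs == genome_set$target_species]
  target_set <- genome_set
  target_set$genomes <- targets
  for (i in seq_len(nrow(pairs))) {
    pp <- as_primer_pair(pairs[i, ])
    specs <- prep_scan(pp, max_mismatch, clamp)
    quick <- vapply(targets, function(g) {
      any_amplicon(g, specs, max_product)
    }, logical(1))
    if (!all(quick)) next
    rep <- insilico_pcr(pp, genome_set, max_mismatch, clamp, max_product)
    if (rep$specific) return(list(pair = pp, report = rep, rank = i))
  }
  stop("no candidate primer pair is specific in silico", call. = FALSE)
}

any_amplicon <- function(genome, specs, max_product) {
  for (gene in names(genome$genes)) {
    sites <- primer_sites(genome$genes[[gene]], specs)
    if (is.null(sites)) next
    plus <- sites[sites$strand == "+", , drop = FALSE]
    minus <- sites[sites$strand == "-", , drop = FALSE]
    for (i in seq_len(nrow(plus))) {
      ok <- minus$start > plus$end[i] &
        (minus$end - plus$start[i] + 1L) <= max_product
      if (any(ok)) return(TRUE)
    }
  }
  FALSE
}

#' Write the primer table and specificity report
#'
#' The primer table follows the conventional assay-table schema: primer name,
#' 5'->3' sequence, product size.
#'
#' @param pair a `primer_pair`.
#' @param report a `specificity_report`.
#' @param path output path.
#' @param name assay name stem used for the primer names (default "marker").
#' @return `path`, invisibly.
#' @export
write_primer_table <- function(pair, path, name = "marker") {
  df <- data.frame(name = paste0(name, c("-F", "-R")),
                   sequence_5to3 = c(pair$forward_seq, pair$reverse_seq),
                   length_nt = c(nchar(pair$forward_seq), nchar(pair$reverse_seq)),
                   gc = c(pair$forward_gc, pair$reverse_gc),
                   tm_wallace = c(pair$forward_tm, pair$reverse_tm),
                   product_size_bp = pair$product_size,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_primer_table
#' @export
write_specificity_report <- function(report, path) {
  write_tsv(report$verdicts, path)
}
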