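# Pairwise global alignment and the k-mer prefilter.
#
# Scoring convention: match/mismatch scores plus affine gap penalties where a
# gap run of length L costs gap_open + L * gap_extend. Identity is
# matches / alignment columns, terminal gaps included, so it is a global
# (end-to-end) measure in [0, 1] and symmetric in its arguments.

default_scoring <- function() {
  list(match = 1L, mismatch = -1L, gap_open = 10L, gap_extend = 1L)
}

check_scoring <- function(scoring) {
  sc <- modifyList(default_scoring(), as.list(scoring))
  stopifnot(sc$match > 0, sc$mismatch <= 0, sc$gap_open >= 0, sc$gap_extend >= 0)
  lapply(sc, as.integer)
}

#' Global pairwise sequence identity
#'
#' Needleman–Wunsch global alignment with affine gaps; identity is the number
#' of match columns divided by the total number of alignment columns
#' (terminal gaps count). Among score-optimal alignments the one with the
#' most matches is reported, so the value is deterministic.
#'
#' @param seq_a,seq_b non-empty sequences (single strings).
#' @param scoring list overriding any of `match` (default `1`), `mismatch`
#'   (`-1`), `gap_open` (`10`), `gap_extend` (`1`); penalties positive.
#' @param nucleotide if `TRUE` (default) compare as DNA where any character
#'   outside A/C/G/T (e.g. `N`) matches nothing; if `FALSE` compare raw
#'   characters (protein mode, `X`/`*` match nothing).
#' @param details if `TRUE` return a list with `identity`, `matches`,
#'   `columns` and `score` instead of the bare identity.
#' @return numeric identity in `[0, 1]`, or a list when `details = TRUE`.
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT")   # 1
#' pairwise_identity("AAAA", "AAAT")           # 0.75
#' pairwise_identity("ACGTACGTAC", "ACGTTCGTAC") # 0.9
#' @export
pairwise_identity <- function(seq_a, seq_b, scoring = list(),
                              nucleotide = TRUE, details = FALSE) {
  stopifnot(is.character(seq_a), length(seq_a) == 1L,
            is.character(seq_b), length(seq_b) == 1L)
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("cannot align an empty sequence", call. = FALSE)
  sc <- check_scoring(scoring)
  res <- .nw_identity_cpp(toupper(seq_a), toupper(seq_b), sc$match, sc$mismatch,
                          sc$gap_open, sc$gap_extend, nucleotide)
  if (details) res else res$identity
}

#' Global pairwise alignment with traceback
#'
#' As [pairwise_identity()] but returns the aligned sequences (gap character
#' `-`), used e.g. to project cluster members onto their representative's
#' coordinates.
#'
#' @inheritParams pairwise_identity
#' @return list with `aligned_a`, `aligned_b`, `identity`, `matches`,
#'   `columns`, `score`.
#' @export
pairwise_alignment <- function(seq_a, seq_b, scoring = list(), nucleotide = TRUE) {
  stopifnot(is.character(seq_a), length(seq_a) == 1L,
            is.character(seq_b), length(seq_b) == 1L)
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("cannot align an empty sequence", call. = FALSE)
  sc <- check_scoring(scoring)
  .nw_align_cpp(toupper(seq_a), toupper(seq_b), sc$match, sc$mismatch,
                sc$gap_open, sc$gap_extend, nucleotide)
}

#' Conservative k-mer prefilter for an identity cutoff
#'
#' Decides cheaply whether a pair of sequences could possibly reach
#' `identity >= cutoff`. The test is conservative: it never returns `FALSE`
#' for a pair whose alignment identity is at least the cutoff. It combines
#' two provable bounds: identity cannot exceed `len_short / len_long`
#' (matches are at most `len_short`, columns at least `len_long`), and an
#' alignment with at most `m` non-match columns destroys at most `k * m` of
#' the shorter sequence's k-mers, so at least
#' `(len_short - k + 1) - k * m` shared k-mers must remain, with the
#' non-match budget `m = floor((1 - cutoff) * (len_a + len_b))`. Whenever
#' that threshold is non-positive the filter passes the pair (it can prove
#' nothing) — which is the common case at permissive cutoffs; the bound only
#' bites at high cutoffs.
#'
#' @param seq_a,seq_b nucleotide sequences (single strings).
#' @param k k-mer size, at least 4 (default 8). k-mers containing `N` are
#'   ignored.
#' @param cutoff identity cutoff in `(0, 1]` the pair is tested against.
#' @return `TRUE` if the pair may reach the cutoff, `FALSE` if it provably
#'   cannot.
#' @export
kmer_prefilter <- function(seq_a, seq_b, k = 8L, cutoff = 0.5) {
  stopifnot(k >= 4L, cutoff > 0, cutoff <= 1)
  la <- nchar(seq_a); lb <- nchar(seq_b)
  ls <- min(la, lb); ll <- max(la, lb)
  if (ls / ll < cutoff) return(FALSE)
  budget <- floor((1 - cutoff) * (la + lb))
  threshold <- (ls - k + 1) - k * budget
  if (threshold <= 0) return(TRUE)
  shared <- .shared_kmer_count_cpp(toupper(seq_a), toupper(seq_b), as.integer(k))
  shared >= threshold
}

#' Translate CDS nucleotide sequences to amino acids
#'
#' Standard genetic code, frame 0; trailing bases beyond the last full codon
#' are dropped, and fuzzy codons (containing `N`) translate to `X`.
#'
#' @param seq character vector of nucleotide sequences.
#' @return character vector of amino-acid sequences.
#' @export
translate_cds <- function(seq) {
  stopifnot(is.character(seq))
  vapply(seq, function(s) {
    s <- normalize_seq(s)
    n <- 3L * (nchar(s) %/% 3L)
    if (n < 3L) stop("sequence shorter than one codon", call. = FALSE)
    aa <- Biostrings::translate(Biostrings::DNAString(substr(s, 1L, n)),
                                if.fuzzy.codon = "solve")
    as.character(aa)
  }, character(1), USE.NAMES = FALSE)
}
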