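# small shared helpers

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so seeded package internals never disturb the caller's
#' random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic, locale-independent ordering of character keys
order_c <- function(...) order(..., method = "radix")

#' Reverse complement of nucleotide sequences
#'
#' Accepts a character vector over `A`, `C`, `G`, `T`, `N` (case-insensitive;
#' `U` is mapped to `T`).
#'
#' @param seq character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @examples
#' reverse_complement("AAATTTGGG")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  out <- vapply(seq, function(s) {
    s <- chartr("uU", "tT", s)
    r <- rev(charToRaw(chartr("ACGTacgtNn", "TGCAtgcaNn", s)))
    rawToChar(r)
  }, character(1), USE.NAMES = FALSE)
  toupper(out)
}

# write a data.frame as a deterministic TSV (header, no quotes, no rownames)
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
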