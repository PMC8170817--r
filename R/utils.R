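# Shared low-level helpers: base encoding, reverse complement, fast string
# assembly. The integer base code is the package-wide convention:
#   0 = '-' (gap, a recovered deletion; carries no base evidence)
#   1..5 = A, C, G, T, N
BASE_CHARS <- c("A", "C", "G", "T", "N")
GAP_CHAR <- "-"
CELL_CHARS <- c(GAP_CHAR, BASE_CHARS)

# utf8 codepoints of the cell alphabet, indexed by code + 1
CELL_UTF8 <- vapply(CELL_CHARS, utf8ToInt, integer(1))

encode_cells <- function(chars) {
  code <- match(chars, BASE_CHARS)
  code[is.na(code) & chars == GAP_CHAR] <- 0L
  if (anyNA(code)) {
    bad <- unique(chars[is.na(code)])
    abort(paste0("invalid sequence character(s): ", paste(bad, collapse = " ")))
  }
  code
}

# Collapse a code vector into strings split at `lens` boundaries.
# Single intToUtf8 call + vectorized substring: fast for millions of cells.
codes_to_strings <- function(code, lens) {
  if (length(code) == 0L) return(character(length(lens)))
  big <- intToUtf8(CELL_UTF8[code + 1L])
  ends <- cumsum(lens)
  substring(big, ends - lens + 1L, ends)
}

split_cells <- function(x) strsplit(x, "", fixed = TRUE)

#' Reverse-complement nucleotide sequences
#'
#' Vectorised over a character vector; `N` maps to `N` and the gap symbol
#' `-` is preserved.
#'
#' @param x character vector of sequences over `{A,C,G,T,N,-}`.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGTN", "AA-T"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(chars) chartr("ACGTN", "TGCAN", chars)

check_dna <- function(seq, what = "sequence") {
  bad <- grepl(paste0("[^", paste(BASE_CHARS, collapse = ""), "]"), seq)
  if (any(bad)) {
    abort(paste0(what, " contains characters outside {A,C,G,T,N} at record(s) ",
                 paste(utils::head(which(bad), 5), collapse = ", ")))
  }
  invisible(seq)
}

# Derive a reproducible child seed from a user seed and a stream label,
# staying below .Machine$integer.max.
child_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + (sum(utf8ToInt(stream)) %% 1009L)
}
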