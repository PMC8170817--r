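# Column dominance: a column of the alignment array is "dominated" by the
# m most frequent (non-N) base types if the remaining bases together number
# at most `minor_count` (default 3), or make up at most `minor_frac`
# (default 2%) of a column with at least `min_depth_for_frac` (default 100)
# bases. The smallest admissible m in {1,2,3} wins; otherwise the column is
# four-type dominated and receives no correction. N never dominates; gap
# cells carry no base evidence.

dominance_params <- function(minor_count = 3, minor_frac = 0.02,
                             min_depth_for_frac = 100) {
  list(minor_count = minor_count, minor_frac = minor_frac,
       min_depth_for_frac = min_depth_for_frac)
}

# Vectorised classifier over a counts matrix (n_cols x 5, columns A,C,G,T,N).
# Returns a list of integer vectors: dominance (1-4, NA for depth 0),
# top1..top3 (base codes ranked by count, ties broken A<C<G<T), depth.
classify_columns <- function(counts, params = dominance_params()) {
  stopifnot(ncol(counts) == 5L)
  ncol_arr <- nrow(counts)
  depth <- rowSums(counts)
  acgt <- counts[, 1:4, drop = FALSE]
  # rank 4 values per row; key encodes count then fixed base order
  key <- acgt * 8L
  key <- key + matrix(rep(c(3L, 2L, 1L, 0L), each = ncol_arr), ncol_arr, 4L)
  i <- seq_len(ncol_arr)
  top1 <- max.col(key, ties.method = "first")
  key[cbind(i, top1)] <- -1L
  top2 <- max.col(key, ties.method = "first")
  key[cbind(i, top2)] <- -1L
  top3 <- max.col(key, ties.method = "first")
  c1 <- acgt[cbind(i, top1)]
  c2 <- acgt[cbind(i, top2)]
  c3 <- acgt[cbind(i, top3)]
  minor_ok <- function(minor) {
    minor <= params$minor_count |
      (depth >= params$min_depth_for_frac & minor / pmax(depth, 1) <= params$minor_frac)
  }
  m1 <- c1 > 0L & minor_ok(depth - c1)
  m2 <- c2 > 0L & minor_ok(depth - c1 - c2)
  m3 <- c3 > 0L & minor_ok(depth - c1 - c2 - c3)
  dominance <- ifelse(m1, 1L, ifelse(m2, 2L, ifelse(m3, 3L, 4L)))
  dominance[depth == 0L] <- NA_integer_
  list(dominance = dominance, top1 = top1, top2 = top2, top3 = top3,
       depth = depth)
}

#' Classify the dominance of one alignment-array column
#'
#' @param counts named integer vector of base counts over `A,C,G,T,N`
#'   (missing names count zero).
#' @param minor_count maximum absolute count of non-dominant bases (default 3).
#' @param minor_frac maximum fraction of non-dominant bases in deep columns
#'   (default 0.02, inclusive).
#' @param min_depth_for_frac minimum column depth for the fractional rule to
#'   apply (default 100, inclusive).
#' @return a list with `dominance` (1-4), `dominant_types` (bases by
#'   descending frequency, ties in fixed order A<C<G<T) and `minor_types`.
#' @export
#' @examples
#' classify_dominance(c(A = 198, T = 1, G = 1))
classify_dominance <- function(counts, minor_count = 3, minor_frac = 0.02,
                               min_depth_for_frac = 100) {
  full <- stats::setNames(integer(5), BASE_CHARS)
  full[names(counts)] <- as.integer(counts)
  if (sum(full) == 0L) abort("cannot classify a column with zero depth")
  cls <- classify_columns(matrix(full, nrow = 1L),
                          dominance_params(minor_count, minor_frac,
                                           min_depth_for_frac))
  d <- cls$dominance
  tops <- c(cls$top1, cls$top2, cls$top3)
  tops <- c(tops, 10L - sum(tops))
  dom <- if (d == 4L) {
    BASE_CHARS[tops[full[tops] > 0L]] # all positive ACGT types, ranked
  } else {
    BASE_CHARS[tops[seq_len(d)]]
  }
  list(
    dominance = as.integer(d),
    dominant_types = dom,
    minor_types = setdiff(BASE_CHARS[full > 0L], dom)
  )
}

#' Per-column base profiles of an alignment array
#'
#' @param array an [build_alignment_array()] object.
#' @inheritParams classify_dominance
#' @return a tibble with one row per covered column: `col` (0-based),
#'   `depth`, counts `A`,`C`,`G`,`T`,`N`, `dominance`, and `dominant_types`
#'   (a list-column of bases by descending frequency).
#' @export
column_profiles <- function(array, minor_count = 3, minor_frac = 0.02,
                            min_depth_for_frac = 100) {
  eng <- array_engine(array)
  params <- dominance_params(minor_count, minor_frac, min_depth_for_frac)
  pr <- profile_columns(eng, params)
  covered <- which(pr$depth > 0L)
  dom_types <- lapply(covered, function(j) {
    d <- pr$dominance[j]
    tops <- c(pr$top1[j], pr$top2[j], pr$top3[j], pr$top4[j])
    if (d == 4L) BASE_CHARS[tops[pr$counts[j, tops] > 0L]]
    else BASE_CHARS[tops[seq_len(d)]]
  })
  tibble(
    col = covered - 1L,
    depth = pr$depth[covered],
    A = pr$counts[covered, 1L], C = pr$counts[covered, 2L],
    G = pr$counts[covered, 3L], T = pr$counts[covered, 4L],
    N = pr$counts[covered, 5L],
    dominance = pr$dominance[covered],
    dominant_types = dom_types
  )
}
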