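# Evaluation of an error corrector against a simulation truth log:
# per-base TP/FP/TN/FN tallies and the precision / recall / gain metrics.
#
# Per base of each evaluated read:
#   injected error, corrected to the true base          -> TP
#   injected error, left as observed                    -> FN
#   injected error, changed to a different wrong base   -> FN + FP
#   correct base, changed                               -> FP
#   correct base, untouched                             -> TN
# Reads removed as 'out' are excluded from the tallies (they no longer
# exist in the corrected set) and are reported separately.

#' Tally correction outcomes against a truth log
#'
#' @param original reads before correction (`read_id`, `seq`).
#' @param corrected reads after correction (`read_id`, `seq`); reads absent
#'   from `corrected` (e.g. removed as 'out') are excluded from the tallies.
#' @param truth truth log tibble (`read_id`, `pos_in_read` 0-based,
#'   `true_base`, `observed_base`), in read orientation. Every `read_id` it
#'   mentions must exist in `original`.
#' @return a one-row tibble with `tp`, `fp`, `tn`, `fn`, `n_reads`,
#'   `n_excluded` (reads present in `original` but not `corrected`).
#' @export
tally_corrections <- function(original, corrected, truth) {
  unknown <- setdiff(unique(truth$read_id), original$read_id)
  if (length(unknown) > 0L) {
    abort(paste0("truth log references unknown read id(s): ",
                 paste(utils::head(unknown, 3), collapse = ", ")))
  }
  m <- match(corrected$read_id, original$read_id)
  if (anyNA(m)) {
    abort("corrected set contains read ids absent from the original set")
  }
  orig_seq <- original$seq[m]
  corr_seq <- corrected$seq
  if (any(nchar(orig_seq) != nchar(corr_seq))) {
    abort("corrected read length differs from original (indels are not evaluated)")
  }
  total_bases <- sum(nchar(corr_seq))
  total_diffs <- sum(hamming_pairs(orig_seq, corr_seq))

  tr <- truth[truth$read_id %in% corrected$read_id, , drop = FALSE]
  n_truth <- nrow(tr)
  tp <- fn <- wrong <- 0L
  diffs_at_truth <- 0L
  if (n_truth > 0L) {
    ri <- match(tr$read_id, corrected$read_id)
    cb <- substr(corr_seq[ri], tr$pos_in_read + 1L, tr$pos_in_read + 1L)
    ob <- substr(orig_seq[ri], tr$pos_in_read + 1L, tr$pos_in_read + 1L)
    if (any(ob != tr$observed_base)) {
      abort("truth log does not match the original reads")
    }
    tp <- sum(cb == tr$true_base)
    unchanged <- sum(cb == tr$observed_base)
    wrong <- n_truth - tp - unchanged
    fn <- unchanged + wrong
    diffs_at_truth <- n_truth - unchanged
  }
  fp_clean <- total_diffs - diffs_at_truth
  tibble(
    tp = as.integer(tp),
    fp = as.integer(fp_clean + wrong),
    tn = as.integer(total_bases - n_truth - fp_clean),
    fn = as.integer(fn),
    n_reads = nrow(corrected),
    n_excluded = nrow(original) - nrow(corrected)
  )
}

#' Precision, recall and gain of an error corrector
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), gain = (TP-FP)/(TP+FN),
#' all reported as percentages. Gain is the net fraction of errors removed
#' without introducing new ones and can be negative. Zero denominators use
#' defined sentinels: precision is 100 when nothing was changed; recall and
#' gain are 100 when there was nothing to correct and nothing was broken,
#' and gain is `NA` when there were no errors but false positives exist.
#' The `sentinel` flag marks rows where any sentinel fired.
#'
#' @param counts a tally tibble from [tally_corrections()] (columns `tp`,
#'   `fp`, `fn`; extra columns are carried through).
#' @return `counts` with added columns `precision`, `recall`, `gain`
#'   (percent) and `sentinel` (logical).
#' @export
correction_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  precision <- ifelse(tp + fp == 0L, 100, 100 * tp / (tp + fp))
  recall <- ifelse(tp + fn == 0L, 100, 100 * tp / (tp + fn))
  gain <- ifelse(tp + fn == 0L,
                 ifelse(fp == 0L, 100, NA_real_),
                 100 * (tp - fp) / (tp + fn))
  mutate(counts,
         precision = precision, recall = recall, gain = gain,
         sentinel = (tp + fp == 0L) | (tp + fn == 0L))
}

#' Base-by-base comparison of a consensus against the true sequence
#'
#' Sequences are compared over their common length; overhanging bases count
#' as differences. The label is `"M"` for a perfect match, otherwise
#' `"d/L"` (d differing bases out of L).
#'
#' @param consensus,truth_seq two nucleotide strings.
#' @return a list with `diffs`, `length` and `label`.
#' @export
#' @examples
#' compare_sequences("ACGT", "ACGT") # "M"
compare_sequences <- function(consensus, truth_seq) {
  n1 <- nchar(consensus); n2 <- nchar(truth_seq)
  common <- min(n1, n2)
  d <- abs(n1 - n2)
  if (common > 0L) {
    d <- d + hamming_pairs(substr(consensus, 1L, common),
                           substr(truth_seq, 1L, common))
  }
  L <- max(n1, n2)
  list(diffs = as.integer(d), length = as.integer(L),
       label = if (d == 0L) "M" else paste0(d, "/", L))
}
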