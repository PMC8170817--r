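# The corrector: stack the extracted reads into a position-sorted alignment
# array, classify column dominance, score minor bases by f + p, and correct
# conservatively row by row (at most the first 2% of a read's bases per
# pass). Reads whose low-ranked bases look like consistent disagreement with
# the gene (repeat contamination) are labeled 'out' and dropped.

#' Build the alignment array
#'
#' Rows are the extracted reads, stably sorted by start offset; columns are
#' positions of the extended gene reference.
#'
#' @param subset a mapped-read tibble from [extract_subset()] or
#'   [read_sam()].
#' @param ext_ref an [extend_reference()] object.
#' @return an object of class `alignment_array`: a list with `ext_ref`,
#'   `rows` (the sorted tibble) and `n_cols`.
#' @export
build_alignment_array <- function(subset, ext_ref) {
  stopifnot(inherits(ext_ref, "extended_reference"))
  n_cols <- nchar(ext_ref$ext_seq)
  if (nrow(subset) > 0L) {
    over <- subset$offset < 0L | subset$offset + nchar(subset$cells) > n_cols
    if (any(over)) {
      abort(paste0("mapped read '", subset$read_id[which(over)[1]],
                   "' overruns the ", n_cols, "-column array"))
    }
    subset <- subset[order(subset$offset), ] # stable: ties keep input order
  }
  structure(list(ext_ref = ext_ref, rows = subset, n_cols = n_cols),
            class = "alignment_array")
}

#' @export
print.alignment_array <- function(x, ...) {
  cat("<alignment_array> ", nrow(x$rows), " reads x ", x$n_cols,
      " columns (", x$ext_ref$gene_id, ")\n", sep = "")
  invisible(x)
}

# ---- internal engine -------------------------------------------------------
# Long-vector representation of the array: one entry per cell.
array_engine <- function(array) {
  rows <- array$rows
  lens <- nchar(rows$cells)
  code <- if (nrow(rows) == 0L) integer(0) else
    encode_cells(unlist(split_cells(rows$cells), use.names = FALSE))
  list(
    row = rep(seq_len(nrow(rows)), lens),
    col = as.integer(rows$offset[rep(seq_len(nrow(rows)), lens)] +
                       sequence(lens)), # 1-based column
    code = code,
    lens = lens,
    n_cols = array$n_cols,
    n_rows = nrow(rows)
  )
}

profile_columns <- function(eng, params = dominance_params()) {
  nz <- eng$code > 0L
  idx <- (eng$col[nz] - 1L) * 5L + eng$code[nz]
  counts <- matrix(tabulate(idx, nbins = eng$n_cols * 5L),
                   nrow = eng$n_cols, ncol = 5L, byrow = TRUE)
  cls <- classify_columns(counts, params)
  cls$counts <- counts
  cls$top4 <- 10L - cls$top1 - cls$top2 - cls$top3
  cls
}

#' Annotate correction-candidate bases
#'
#' Every minor-type cell in a dominance-1/2/3 column receives the priority
#' `p` of its column (0.1, 0.2 or 0.3) and the score `f + p`, where `f` is
#' the frequency of the cell's base type in its column. Dominant-type cells
#' and cells in four-type columns are never candidates and are not listed.
#'
#' @param array an [build_alignment_array()] object.
#' @inheritParams classify_dominance
#' @return a tibble with one row per scored cell: `read_id`, `row` (1-based
#'   row in the array), `col` (0-based), `base`, `f`, `p`, `score`.
#' @export
annotate_bases <- function(array, minor_count = 3, minor_frac = 0.02,
                           min_depth_for_frac = 100) {
  eng <- array_engine(array)
  pr <- profile_columns(eng, dominance_params(minor_count, minor_frac,
                                              min_depth_for_frac))
  sc <- scored_cells(eng, pr)
  tibble(
    read_id = array$rows$read_id[eng$row[sc$idx]],
    row = eng$row[sc$idx],
    col = eng$col[sc$idx] - 1L,
    base = CELL_CHARS[eng$code[sc$idx] + 1L],
    f = sc$f, p = sc$p, score = sc$score
  )
}

scored_cells <- function(eng, pr) {
  d <- pr$dominance[eng$col]
  dd <- ifelse(is.na(d), 0L, d)
  is_dom <- (eng$code == pr$top1[eng$col] & dd >= 1L) |
    (eng$code == pr$top2[eng$col] & dd >= 2L) |
    (eng$code == pr$top3[eng$col] & dd >= 3L)
  idx <- which(eng$code > 0L & dd >= 1L & dd <= 3L & !is_dom)
  cold <- eng$col[idx]
  f <- pr$counts[(eng$code[idx] - 1L) * eng$n_cols + cold] / pr$depth[cold]
  p <- 0.1 * dd[idx]
  list(idx = idx, f = f, p = p, score = f + p, dominance = dd[idx])
}

#' Proportionally assign replacement bases in a two/three-type column
#'
#' The candidate cells of one column are partitioned among the dominant
#' types in proportion to their renormalised frequencies using
#' largest-remainder rounding. A candidate with a phasing preference (its
#' read matches one dominant haplotype at a neighbouring two/three-type
#' column) receives its preferred type while that type's quota lasts;
#' residual ties are resolved by a seeded deterministic shuffle.
#'
#' @param candidates identifiers of the candidate cells (any vector).
#' @param freqs named numeric vector of dominant-type frequencies.
#' @param preferred optional character vector (same length as `candidates`)
#'   of preferred dominant types, `NA` for no preference.
#' @param seed integer seed for the tie-breaking shuffle.
#' @return a character vector of replacement bases, named by `candidates`.
#' @export
#' @examples
#' table(proportional_assignment(1:98, c(T = 0.40, G = 0.58)))
proportional_assignment <- function(candidates, freqs, preferred = NULL,
                                    seed = 42) {
  k <- length(candidates)
  if (k == 0L) return(stats::setNames(character(0), character(0)))
  types <- names(freqs)
  stopifnot(!is.null(types), all(freqs >= 0), sum(freqs) > 0)
  # fixed processing order of types: descending frequency, then A<C<G<T
  ord_t <- order(-freqs, match(types, BASE_CHARS))
  types <- types[ord_t]
  freqs <- freqs[ord_t]
  share <- freqs / sum(freqs)
  quota <- floor(k * share)
  rem <- k - sum(quota)
  if (rem > 0L) {
    frac <- k * share - quota
    give <- order(-frac, -share, match(types, BASE_CHARS))[seq_len(rem)]
    quota[give] <- quota[give] + 1L
  }
  quota <- stats::setNames(as.integer(quota), types)
  if (is.null(preferred)) preferred <- rep(NA_character_, k)
  ord_c <- withr::with_seed(seed, sample.int(k))
  out <- rep(NA_character_, k)
  for (i in ord_c) {
    pref <- preferred[i]
    if (!is.na(pref) && !is.na(quota[pref]) && quota[pref] > 0L) {
      out[i] <- pref
      quota[pref] <- quota[pref] - 1L
    }
  }
  for (i in ord_c) {
    if (is.na(out[i])) {
      j <- which.max(quota) # ties: first = most frequent type
      out[i] <- types[j]
      quota[j] <- quota[j] - 1L
    }
  }
  stats::setNames(out, as.character(candidates))
}

# Phasing preference for candidates of a dominance-2/3 column: look at the
# nearest other dominance-2/3 column within `window` covered by the same
# read with a dominant base there, and prefer the dominant type at `c` that
# co-occurs most often with that neighbour base across reads.
neighbor_preference <- function(cand_rows, c, d23cols, cell_lookup, dom_at,
                                window = 50L) {
  neigh <- d23cols[d23cols != c & abs(d23cols - c) <= window]
  if (length(neigh) == 0L) return(rep(NA_character_, length(cand_rows)))
  neigh <- neigh[order(abs(neigh - c))]
  pref <- rep(NA_character_, length(cand_rows))
  here <- cell_lookup(c)
  for (cn in neigh) {
    there <- cell_lookup(cn)
    dom_n <- dom_at(cn)
    both <- inner_join(here, there, by = "row", suffix = c("", ".n"))
    both <- both[both$base %in% dom_at(c) & both$base.n %in% dom_n, , drop = FALSE]
    if (nrow(both) == 0L) next
    cooc <- table(both$base, both$base.n)
    nb <- there$base[match(cand_rows, there$row)]
    ok <- which(is.na(pref) & !is.na(nb) & nb %in% colnames(cooc) & nb %in% dom_n)
    if (length(ok) > 0L) {
      pick <- vapply(nb[ok], function(b) {
        col <- cooc[, b]
        rownames(cooc)[order(-col, match(rownames(cooc), BASE_CHARS))][1]
      }, character(1))
      pref[ok] <- pick
    }
    if (!anyNA(pref)) break
  }
  pref
}

#' One conservative row-correction pass over an alignment array
#'
#' For each row, the scored cells are ranked ascending by `f + p`; the
#' lowest `ceiling(row_error_fraction * n)` of them (n = read length) are
#' correction candidates. A row with more than one candidate scoring above
#' `out_threshold` is labeled `'out'` (likely a repeat read from elsewhere)
#' and removed without corrections. Remaining candidates are corrected:
#' dominance-1 columns to the dominant base, dominance-2/3 columns by
#' [proportional_assignment()] with neighbour-column phasing, processing
#' dominance-1 columns before 2 before 3.
#'
#' @param array an [build_alignment_array()] object.
#' @param row_error_fraction fraction of a read treated as errors per pass
#'   (default 0.02: at most 2 corrections in a 100 bp read).
#' @param out_threshold score above which a "correction" looks like
#'   consistent disagreement rather than a sequencing error (default 0.2).
#' @inheritParams classify_dominance
#' @param seed integer seed for proportional tie-breaking.
#' @return a list with `array` (corrected, 'out' rows removed), `records`
#'   (a correction-record tibble), and `out_ids`.
#' @export
correct_rows <- function(array, row_error_fraction = 0.02,
                         out_threshold = 0.2, minor_count = 3,
                         minor_frac = 0.02, min_depth_for_frac = 100,
                         seed = 42) {
  rows <- array$rows
  empty_records <- tibble(
    read_id = character(), pos_in_read = integer(), old_base = character(),
    new_base = character(), col = integer(), dominance_at_col = integer()
  )
  if (nrow(rows) == 0L) {
    return(list(array = array, records = empty_records, out_ids = character(0)))
  }
  params <- dominance_params(minor_count, minor_frac, min_depth_for_frac)
  eng <- array_engine(array)
  pr <- profile_columns(eng, params)
  sc <- scored_cells(eng, pr)

  records <- empty_records
  out_rows <- integer(0)
  changed_idx <- integer(0)
  new_code <- integer(0)

  if (length(sc$idx) > 0L) {
    r <- eng$row[sc$idx]
    o <- order(r, sc$score, eng$col[sc$idx])
    r_s <- r[o]
    rank_in_row <- sequence(rle(r_s)$lengths)
    cap <- ceiling(row_error_fraction * nchar(rows$seq))
    is_cand <- rank_in_row <= cap[r_s]
    cand <- o[is_cand] # indices into sc$* vectors
    # 'out' labeling: more than one candidate above the threshold
    over <- sc$score[cand] > out_threshold
    n_over <- tabulate(r[cand][over], nbins = nrow(rows))
    out_rows <- which(n_over > 1L)
    cand <- cand[!(r[cand] %in% out_rows)]

    if (length(cand) > 0L) {
      ci <- sc$idx[cand] # cell indices
      dom_c <- pr$dominance[eng$col[ci]]
      # dominance-1 columns first (priority 1 before 2 before 3)
      d1 <- cand[dom_c == 1L]
      if (length(d1) > 0L) {
        idx1 <- sc$idx[d1]
        changed_idx <- c(changed_idx, idx1)
        new_code <- c(new_code, pr$top1[eng$col[idx1]])
      }
      for (dlev in c(2L, 3L)) {
        dk <- cand[dom_c == dlev]
        if (length(dk) == 0L) next
        idxk <- sc$idx[dk]
        d23cols <- which(!is.na(pr$dominance) &
                           pr$dominance %in% c(2L, 3L) & pr$depth > 0L)
        lookup_cache <- new.env(parent = emptyenv())
        cell_lookup <- function(cc) {
          key <- as.character(cc)
          if (!is.null(lookup_cache[[key]])) return(lookup_cache[[key]])
          at <- which(eng$col == cc & eng$code > 0L)
          val <- tibble(row = eng$row[at], base = BASE_CHARS[eng$code[at]])
          lookup_cache[[key]] <- val
          val
        }
        dom_at <- function(cc) {
          d <- pr$dominance[cc]
          BASE_CHARS[c(pr$top1[cc], pr$top2[cc], pr$top3[cc])[seq_len(min(d, 3L))]]
        }
        for (cc in sort(unique(eng$col[idxk]))) {
          sel <- idxk[eng$col[idxk] == cc]
          dom_types <- dom_at(cc)
          fr <- pr$counts[(match(dom_types, BASE_CHARS) - 1L) * eng$n_cols + cc] /
            pr$depth[cc]
          names(fr) <- dom_types
          pref <- neighbor_preference(eng$row[sel], cc, d23cols,
                                      cell_lookup, dom_at)
          repl <- proportional_assignment(seq_along(sel), fr, preferred = pref,
                                          seed = child_seed(seed, paste0("col", cc)))
          changed_idx <- c(changed_idx, sel)
          new_code <- c(new_code, match(unname(repl), BASE_CHARS))
        }
      }
    }
  }

  # emit records and apply the changes
  if (length(changed_idx) > 0L) {
    keep <- new_code != eng$code[changed_idx]
    changed_idx <- changed_idx[keep]
    new_code <- new_code[keep]
  }
  if (length(changed_idx) > 0L) {
    rowv <- eng$row[changed_idx]
    # 0-based position among the row's non-gap cells, reference orientation
    nz <- as.integer(eng$code > 0L)
    cs <- cumsum(nz)
    starts <- cumsum(eng$lens) - eng$lens
    cs0 <- c(0L, cs)[starts + 1L]
    within0 <- cs[changed_idx] - cs0[rowv] - 1L
    minus <- rows$strand[rowv] == "-"
    read_len <- nchar(rows$seq)[rowv]
    pos_in_read <- ifelse(minus, read_len - 1L - within0, within0)
    old_b <- CELL_CHARS[eng$code[changed_idx] + 1L]
    new_b <- BASE_CHARS[new_code]
    records <- tibble(
      read_id = rows$read_id[rowv],
      pos_in_read = as.integer(pos_in_read),
      old_base = ifelse(minus, comp_base(old_b), old_b),
      new_base = ifelse(minus, comp_base(new_b), new_b),
      col = eng$col[changed_idx] - 1L,
      dominance_at_col = pr$dominance[eng$col[changed_idx]]
    )
    eng$code[changed_idx] <- new_code
  }

  # rebuild rows: apply new cells, drop 'out' rows
  rows$cells <- codes_to_strings(eng$code, eng$lens)
  new_seq <- gsub("-", "", rows$cells, fixed = TRUE)
  flip <- rows$strand == "-"
  new_seq[flip] <- revcomp(new_seq[flip])
  rows$seq <- new_seq
  out_ids <- rows$read_id[out_rows]
  if (length(out_rows) > 0L) rows <- rows[-out_rows, ]
  array$rows <- rows
  list(array = array, records = records, out_ids = out_ids)
}

#' Correct the extracted reads of one gene
#'
#' Iterates the conservative row-correction pass ([correct_rows()]) to a
#' fixpoint: each pass corrects at most the first 2% of a read's bases, the
#' column profiles are recomputed, and the loop stops when a pass changes
#' nothing. Returns the corrected reads, the audit trail of corrections,
#' the ids of removed ('out') reads, and the updated consensus gene
#' sequence.
#'
#' @param subset a mapped-read tibble from [extract_subset()] or
#'   [read_sam()].
#' @param ext_ref an [extend_reference()] object.
#' @inheritParams correct_rows
#' @param max_passes safety bound on the number of passes (default 20).
#' @return an object of class `gene_correction`; see [tidy.gene_correction()]
#'   and [glance.gene_correction()].
#' @export
correct_reads <- function(subset, ext_ref, row_error_fraction = 0.02,
                          out_threshold = 0.2, minor_count = 3,
                          minor_frac = 0.02, min_depth_for_frac = 100,
                          seed = 42, max_passes = 20) {
  array <- build_alignment_array(subset, ext_ref)
  records <- list()
  out_ids <- character(0)
  passes <- 0L
  repeat {
    passes <- passes + 1L
    res <- correct_rows(array, row_error_fraction, out_threshold,
                        minor_count, minor_frac, min_depth_for_frac,
                        seed = child_seed(seed, paste0("pass", passes)))
    array <- res$array
    if (nrow(res$records) > 0L) {
      records[[length(records) + 1L]] <- mutate(res$records, pass = passes)
    }
    out_ids <- c(out_ids, res$out_ids)
    done <- nrow(res$records) == 0L && length(res$out_ids) == 0L
    if (done || passes >= max_passes) break
  }
  records <- if (length(records) > 0L) bind_rows(records) else
    tibble(read_id = character(), pos_in_read = integer(),
           old_base = character(), new_base = character(), col = integer(),
           dominance_at_col = integer(), pass = integer())
  structure(
    list(
      ext_ref = ext_ref,
      array = array,
      reads = select(array$rows, "read_id", "seq", "qual", "mate"),
      records = records,
      out_ids = out_ids,
      consensus = consensus_sequence(array),
      passes = passes,
      params = list(row_error_fraction = row_error_fraction,
                    out_threshold = out_threshold, minor_count = minor_count,
                    minor_frac = minor_frac,
                    min_depth_for_frac = min_depth_for_frac, seed = seed)
    ),
    class = "gene_correction"
  )
}

#' Consensus sequence of a (corrected) alignment array
#'
#' Per column the most frequent non-gap base among retained rows (for
#' two/three-type columns this is the highest-frequency dominant type);
#' zero-coverage columns fall back to the reference base. The flanks are
#' trimmed so the consensus has the core gene length.
#'
#' @param array an [build_alignment_array()] object, normally after
#'   correction.
#' @param trim_flanks drop the flank columns (default `TRUE`).
#' @return a single consensus string.
#' @export
consensus_sequence <- function(array, trim_flanks = TRUE) {
  eng <- array_engine(array)
  pr <- profile_columns(eng)
  ref_chars <- split_cells(array$ext_ref$ext_seq)[[1]]
  top1 <- pr$top1
  acgt_depth <- pr$depth - pr$counts[, 5L]
  out <- ifelse(pr$depth == 0L, ref_chars,
                ifelse(acgt_depth > 0L, BASE_CHARS[top1], "N"))
  full <- paste(out, collapse = "")
  if (!trim_flanks) return(full)
  substr(full, array$ext_ref$flank_left + 1L,
         nchar(full) - array$ext_ref$flank_right)
}

#' @export
print.gene_correction <- function(x, ...) {
  cat("<gene_correction> ", x$ext_ref$gene_id, ": ", nrow(x$reads),
      " reads kept, ", length(x$out_ids), " 'out', ",
      nrow(x$records), " corrections in ", x$passes, " pass(es)\n", sep = "")
  invisible(x)
}

#' Tidy the correction audit trail
#'
#' @param x a [correct_reads()] result.
#' @param ... unused.
#' @return the correction-record tibble (`read_id`, `pos_in_read`,
#'   `old_base`, `new_base`, `col`, `dominance_at_col`, `pass`).
#' @export
tidy.gene_correction <- function(x, ...) x$records

#' One-row summary of a correction run
#'
#' @param x a [correct_reads()] result.
#' @param ... unused.
#' @return a one-row tibble: gene id, reads kept, 'out' reads, corrections,
#'   passes, consensus length.
#' @export
glance.gene_correction <- function(x, ...) {
  tibble(
    gene_id = x$ext_ref$gene_id,
    n_reads = nrow(x$reads),
    n_out = length(x$out_ids),
    n_corrections = nrow(x$records),
    passes = x$passes,
    consensus_len = nchar(x$consensus)
  )
}
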