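# Read extraction: flank-extend the gene reference, then collect every read
# (or its reverse complement) that has an ungapped placement on the extended
# reference at >= 95% identity. Mapping is seed-and-verify: exact k-mer seeds
# sampled along the read against a full k-mer index of the reference, each
# candidate diagonal verified by a full Hamming count.

#' Extend a gene reference with genomic flanks
#'
#' The gene reference is extended at both ends with `flank` bases of genomic
#' context (50 by default) so reads straddling the gene boundary can still be
#' extracted. Flanks are truncated where the source contig ends.
#'
#' @param gene_ref a list or one-row data frame with fields `gene_id`, `seq`,
#'   and optionally `start`/`end` (0-based half-open interval on `genome`).
#' @param genome optional single contig sequence the gene was cut from; when
#'   absent (or no interval is recorded) the flanks are empty.
#' @param flank non-negative number of bases to append on each side.
#' @return an object of class `extended_reference`: a list with `gene_id`,
#'   `core_seq`, `flank_left`, `flank_right`, `ext_seq`.
#' @export
extend_reference <- function(gene_ref, genome = NULL, flank = 50) {
  if (flank < 0) abort("flank must be non-negative")
  gene_ref <- as.list(gene_ref)
  core <- gene_ref$seq
  if (is.null(core) || !nzchar(core)) abort("gene reference sequence is empty")
  left <- right <- ""
  if (!is.null(genome) && !is.null(gene_ref$start) && flank > 0) {
    start <- as.integer(gene_ref$start) # 0-based
    end <- if (!is.null(gene_ref$end)) as.integer(gene_ref$end) else start + nchar(core)
    if (substr(genome, start + 1L, end) != core) {
      abort("gene interval does not match the genome sequence")
    }
    lstart <- max(0L, start - as.integer(flank))
    left <- substr(genome, lstart + 1L, start)
    right <- substr(genome, end + 1L, min(nchar(genome), end + as.integer(flank)))
  }
  structure(
    list(
      gene_id = gene_ref$gene_id %||% "gene",
      core_seq = core,
      flank_left = nchar(left),
      flank_right = nchar(right),
      ext_seq = paste0(left, core, right)
    ),
    class = "extended_reference"
  )
}

#' @export
print.extended_reference <- function(x, ...) {
  cat("<extended_reference> ", x$gene_id, ": ", nchar(x$core_seq),
      " bp core + ", x$flank_left, "/", x$flank_right, " bp flanks\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Index every k-mer of the extended reference.
ref_kmer_index <- function(ext_seq, k) {
  L <- nchar(ext_seq)
  if (L < k) return(tibble(kmer = character(), pos = integer()))
  starts <- seq_len(L - k + 1L)
  tibble(kmer = substring(ext_seq, starts, starts + k - 1L), pos = starts)
}

# Sampled seed start positions for a read of length n: every `step` bases
# plus the final full k-mer window.
seed_starts <- function(n, k, step) {
  if (n < k) return(integer(0))
  unique(c(seq(1L, n - k + 1L, by = step), n - k + 1L))
}

# Disjoint seed windows (plus the final window): with k = 16 a 100 bp read
# has six, so five mismatches always leave at least one clean seed.
disjoint_starts <- function(n, k) {
  if (n < k) return(integer(0))
  unique(c(seq(1L, n - k + 1L, by = k), n - k + 1L))
}

# Candidate diagonals for the given rows: exact matches of seed k-mers
# against the reference index, converted to 0-based offsets.
seed_candidates <- function(seqs, rc, rows, n, idx, k, starts_fun) {
  has_dup <- anyDuplicated(idx$kmer) > 0L
  cand <- list()
  ci <- 0L
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") seqs else rc
    for (len in unique(n[rows])) {
      rr <- rows[n[rows] == len]
      for (s in starts_fun(len, k)) {
        km <- substring(ss[rr], s, s + k - 1L)
        if (!has_dup) {
          m <- match(km, idx$kmer)
          hit <- which(!is.na(m))
          if (length(hit) == 0L) next
          ci <- ci + 1L
          cand[[ci]] <- tibble(row = rr[hit], strand = strand,
                               offset = idx$pos[m[hit]] - s)
        } else {
          hits <- tibble(kmer = km, row = rr) %>%
            inner_join(idx, by = "kmer", relationship = "many-to-many")
          if (nrow(hits) == 0L) next
          ci <- ci + 1L
          cand[[ci]] <- tibble(row = hits$row, strand = strand,
                               offset = hits$pos - s)
        }
      }
    }
  }
  if (ci == 0L) return(tibble(row = integer(), strand = character(),
                              offset = integer()))
  distinct(bind_rows(cand))
}

#' Extract the subset of reads relevant to a target gene
#'
#' Both the read and its reverse complement are tried; the best-scoring
#' ungapped placement with identity at or above `min_identity_pct` is kept
#' (ties broken by smallest offset, then forward strand). The result is
#' sorted by offset (then read id), which is the row order of the alignment
#' array.
#'
#' @param reads a read tibble (`read_id`, `seq`, optional `qual`, `mate`).
#' @param ext_ref an [extend_reference()] object.
#' @param min_identity_pct minimum percent identity of an acceptable
#'   placement (default 95, i.e. at most 5 mismatches in a 100 bp read).
#' @param k seed k-mer length (default 31).
#' @param step spacing of sampled seed k-mers along the read (default 10).
#' @return a mapped-read tibble with columns `read_id`, `seq`, `qual`,
#'   `mate`, `strand`, `offset` (0-based), `cells` (reference-oriented
#'   aligned bases), `mismatches`, `identity_pct`.
#' @export
extract_subset <- function(reads, ext_ref, min_identity_pct = 95,
                           k = 31, step = 10) {
  stopifnot(inherits(ext_ref, "extended_reference"))
  if (nrow(reads) == 0L) return(empty_subset())
  L <- nchar(ext_ref$ext_seq)
  rc <- revcomp(reads$seq)
  n <- nchar(reads$seq)

  verify <- function(cand) {
    cand <- filter(cand, .data$offset >= 0L, .data$offset + n[.data$row] <= L)
    if (nrow(cand) == 0L) return(cand)
    qseq <- ifelse(cand$strand == "+", reads$seq[cand$row], rc[cand$row])
    rseq <- substring(ext_ref$ext_seq, cand$offset + 1L,
                      cand$offset + n[cand$row])
    mm <- hamming_pairs(qseq, rseq)
    len <- n[cand$row]
    ident <- 100 * (len - mm) / len
    keep <- ident >= min_identity_pct
    cand <- cand[keep, ]
    cand$cells <- qseq[keep]
    cand$mismatches <- mm[keep]
    cand$identity_pct <- ident[keep]
    cand
  }

  idx <- ref_kmer_index(ext_ref$ext_seq, k)
  cand <- verify(seed_candidates(reads$seq, rc, seq_len(nrow(reads)), n, idx,
                                 k, function(len, k) seed_starts(len, k, step)))

  # Rescue pass for reads the sampled 31-mer seeds missed: disjoint 16-mer
  # windows guarantee a clean seed for any read with <= 5 mismatches.
  k2 <- 16L
  unplaced <- setdiff(which(n >= k2), unique(cand$row))
  if (length(unplaced) > 0L) {
    idx2 <- ref_kmer_index(ext_ref$ext_seq, k2)
    cand2 <- verify(seed_candidates(reads$seq, rc, unplaced, n, idx2, k2,
                                    disjoint_starts))
    cand <- bind_rows(cand, cand2)
  }
  if (nrow(cand) == 0L) return(empty_subset())

  # best placement per read: highest identity, then smallest offset, then "+"
  best <- cand %>%
    arrange(.data$row, dplyr::desc(.data$identity_pct), .data$offset,
            .data$strand) %>%
    distinct(.data$row, .keep_all = TRUE)

  out <- tibble(
    read_id = reads$read_id[best$row],
    seq = reads$seq[best$row],
    qual = if ("qual" %in% names(reads)) reads$qual[best$row] else NA_character_,
    mate = if ("mate" %in% names(reads)) reads$mate[best$row] else "unpaired",
    strand = best$strand,
    offset = as.integer(best$offset),
    cells = best$cells,
    mismatches = as.integer(best$mismatches),
    identity_pct = best$identity_pct
  )
  arrange(out, .data$offset, .data$read_id)
}

#' Map a single read against an extended reference
#'
#' @inheritParams extract_subset
#' @param read a one-row read tibble, or a list with `read_id` and `seq`.
#' @return a one-row mapped-read tibble, or `NULL` when no placement reaches
#'   `min_identity_pct` (a normal outcome, not an error).
#' @export
map_read <- function(read, ext_ref, min_identity_pct = 95, k = 31, step = 10) {
  read <- as_tibble(as.list(read)[c("read_id", "seq", intersect(names(read), c("qual", "mate")))])
  hit <- extract_subset(read, ext_ref, min_identity_pct, k, step)
  if (nrow(hit) == 0L) NULL else hit
}
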