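# Readers and writers: FASTA (via Biostrings), 4-line FASTQ, SAM import
# (via Rsamtools), and the package's own TSV formats (truth log, extracted
# subset, evaluation report).

fastq_fill_qual <- "I"

open_text <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a FASTA file
#'
#' @param path path to a FASTA file (optionally gzipped).
#' @return a tibble with columns `id` (the first whitespace-delimited token of
#'   the header) and `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(
    id = vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L),
    seq = unname(as.character(x))
  )
}

#' Write sequences to FASTA
#'
#' @param x a tibble/data frame with columns `id` and `seq`, or a named
#'   character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- tibble(id = names(x), seq = unname(x))
  set <- Biostrings::DNAStringSet(x$seq)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a 4-line FASTQ file
#'
#' Records are validated: a quality line whose length differs from its
#' sequence line, or a truncated trailing record, is a parse error naming the
#' offending record index. Read pairing is inferred from trailing `/1` and
#' `/2` id suffixes.
#'
#' @param path path to a FASTQ file (optionally gzipped).
#' @return a tibble with columns `read_id`, `seq`, `qual`, `mate`
#'   (`"first"`, `"second"` or `"unpaired"`). The `/1` `/2` suffix is kept in
#'   `read_id` so ids stay unique.
#' @export
read_fastq <- function(path) {
  con <- open_text(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) {
    return(tibble(read_id = character(), seq = character(),
                  qual = character(), mate = character()))
  }
  if (length(lines) %% 4L != 0L) {
    abort(paste0("truncated FASTQ record at record index ",
                 length(lines) %/% 4L + 1L, " in ", path))
  }
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  bad_hdr <- !startsWith(ids, "@") | !startsWith(plus, "+")
  if (any(bad_hdr)) {
    abort(paste0("malformed FASTQ record at record index ",
                 which(bad_hdr)[1], " in ", path))
  }
  bad_len <- nchar(quals) != nchar(seqs)
  if (any(bad_len)) {
    abort(paste0("quality length differs from sequence length at record index ",
                 which(bad_len)[1], " in ", path))
  }
  ids <- sub("^@", "", ids)
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(seqs)
  check_dna(seqs, "FASTQ sequence")
  mate <- rep("unpaired", length(ids))
  mate[grepl("/1$", ids)] <- "first"
  mate[grepl("/2$", ids)] <- "second"
  tibble(read_id = ids, seq = seqs, qual = quals, mate = mate)
}

#' Write reads to FASTQ
#'
#' Reads without qualities are written with a constant `"I"` quality column
#' (the corrector never uses qualities; a fixed fill keeps the FASTQ valid).
#' With two output paths, mates `"first"`/`"second"` are written to the two
#' files in synchronized order.
#'
#' @param reads a tibble with columns `read_id`, `seq` and optionally `qual`
#'   and `mate`.
#' @param path one output path, or two paths for paired output.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else rep(NA_character_, nrow(reads))
  qual[is.na(qual)] <- strrep(fastq_fill_qual, nchar(reads$seq[is.na(qual)]))
  recs <- function(i) {
    if (length(i) == 0L) return(character(0))
    as.vector(rbind(paste0("@", reads$read_id[i]), reads$seq[i], "+", qual[i]))
  }
  if (length(path) == 2L) {
    if (!"mate" %in% names(reads)) {
      abort("paired FASTQ output needs a 'mate' column")
    }
    i1 <- which(reads$mate == "first")
    i2 <- which(reads$mate == "second")
    for (k in 1:2) {
      con <- open_text(path[k], "wt")
      writeLines(recs(list(i1, i2)[[k]]), con)
      close(con)
    }
  } else {
    con <- open_text(path, "wt")
    writeLines(recs(seq_len(nrow(reads))), con)
    close(con)
  }
  invisible(path)
}

#' Import a SAM alignment against the extended gene reference
#'
#' Converts each aligned record into the internal mapped-read representation:
#' SAM's 1-based `POS` becomes a 0-based column offset, CIGAR insertions and
#' soft clips are removed from the read, and deletions are recovered as gap
#' cells `-`. Unmapped, secondary and supplementary records are skipped.
#' Reverse-strand records are used as stored (already reference-oriented).
#'
#' @param path path to a text SAM (or BAM) file.
#' @param ext_ref an [extend_reference()] object the alignments refer to.
#' @return a mapped-read tibble as produced by [extract_subset()], sorted by
#'   `offset` then `read_id`.
#' @export
read_sam <- function(path, ext_ref) {
  stopifnot(inherits(ext_ref, "extended_reference"))
  bam <- path
  n_lines <- NA_integer_
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    n_lines <- sum(!startsWith(readLines(path), "@"))
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "cigar", "seq", "qual", "strand")
  )
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (!is.na(n_lines) && length(rec$qname) < n_lines) {
    abort(paste0(n_lines - length(rec$qname), " SAM record(s) in ", path,
                 " were rejected (CIGAR/sequence length inconsistency?)"))
  }
  keep <- !is.na(rec$pos) &
    !bitwAnd(rec$flag, 4L) & !bitwAnd(rec$flag, 256L) & !bitwAnd(rec$flag, 2048L)
  if (!any(keep)) {
    return(empty_subset())
  }
  qname <- rec$qname[keep]
  flag <- rec$flag[keep]
  pos <- rec$pos[keep]
  cigar <- rec$cigar[keep]
  seq <- as.character(rec$seq)[keep]
  qual <- as.character(rec$qual)[keep]
  mate <- rep("unpaired", length(qname))
  mate[bitwAnd(flag, 64L) > 0L] <- "first"
  mate[bitwAnd(flag, 128L) > 0L] <- "second"
  mate_suffix <- c(first = "/1", second = "/2", unpaired = "")[mate]
  read_id <- ifelse(endsWith(qname, mate_suffix), qname, paste0(qname, mate_suffix))

  cells <- character(length(qname))
  for (i in seq_along(qname)) {
    cells[i] <- cigar_to_cells(seq[i], cigar[i])
  }
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  offset <- pos - 1L
  over <- offset + nchar(cells) > nchar(ext_ref$ext_seq)
  if (any(over)) {
    abort(paste0("SAM record '", read_id[which(over)[1]],
                 "' extends past the extended reference"))
  }
  ref_cells <- substring(ext_ref$ext_seq, offset + 1L, offset + nchar(cells))
  mm <- hamming_pairs(cells, ref_cells)
  aligned <- nchar(cells)
  # The read in its original orientation (insertions/clips already dropped).
  orig_seq <- gsub("-", "", cells, fixed = TRUE)
  orig_qual <- qual
  flip <- strand == "-"
  orig_seq[flip] <- revcomp(orig_seq[flip])
  orig_qual[flip] <- vapply(strsplit(orig_qual[flip], ""), function(q)
    paste(rev(q), collapse = ""), character(1))
  tibble(
    read_id = read_id, seq = orig_seq, qual = orig_qual, mate = mate,
    strand = strand, offset = as.integer(offset), cells = cells,
    mismatches = mm, identity_pct = 100 * (aligned - mm) / aligned
  ) %>%
    arrange(.data$offset, .data$read_id)
}

# Apply the indel policy to one SAM record: M/=/X kept, I and S dropped,
# D filled with '-', H/P ignored. Errors on length inconsistency.
cigar_to_cells <- function(seq, cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (length(toks) == 0L) abort(paste0("unparsable CIGAR '", cigar, "'"))
  lens <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^\\d+", "", toks)
  out <- character(length(toks))
  qpos <- 1L
  for (j in seq_along(toks)) {
    L <- lens[j]
    if (op[j] %in% c("M", "=", "X")) {
      out[j] <- substr(seq, qpos, qpos + L - 1L)
      qpos <- qpos + L
    } else if (op[j] %in% c("I", "S")) {
      qpos <- qpos + L # dropped from the alignment
    } else if (op[j] == "D" || op[j] == "N") {
      out[j] <- strrep("-", L)
    } # H, P consume nothing
  }
  if (qpos - 1L != nchar(seq)) {
    abort(paste0("CIGAR '", cigar, "' is inconsistent with a ",
                 nchar(seq), " bp sequence"))
  }
  paste(out, collapse = "")
}

# Hamming distance between equal-length string pairs, vectorised; gap cells
# always count as mismatches against the reference.
hamming_pairs <- function(a, b) {
  stopifnot(all(nchar(a) == nchar(b)))
  if (length(a) == 0L) return(integer(0))
  n <- nchar(a)
  out <- integer(length(a))
  for (len in unique(n)) {
    i <- which(n == len)
    if (len == 0L) next
    A <- matrix(unlist(split_cells(a[i]), use.names = FALSE), nrow = len)
    B <- matrix(unlist(split_cells(b[i]), use.names = FALSE), nrow = len)
    out[i] <- colSums(A != B)
  }
  out
}

empty_subset <- function() {
  tibble(
    read_id = character(), seq = character(), qual = character(),
    mate = character(), strand = character(), offset = integer(),
    cells = character(), mismatches = integer(), identity_pct = double()
  )
}

#' Read / write the simulation truth log
#'
#' The truth log is a TSV with columns `read_id`, `pos_in_read` (0-based,
#' in the read's own orientation), `true_base`, `observed_base`.
#'
#' @param path file path.
#' @return `read_truth()` returns the truth tibble.
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "integer",
                                               "character", "character"))
  as_tibble(df)
}

#' @param truth a truth tibble.
#' @rdname read_truth
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an extracted subset TSV
#'
#' @param path file path.
#' @return `read_subset()` returns a mapped-read tibble.
#' @export
read_subset <- function(path) {
  df <- utils::read.delim(path, colClasses = c(
    read_id = "character", seq = "character", qual = "character",
    mate = "character", strand = "character", offset = "integer",
    cells = "character", mismatches = "integer", identity_pct = "numeric"
  ))
  as_tibble(df)
}

#' @param subset a mapped-read tibble from [extract_subset()] or [read_sam()].
#' @rdname read_subset
#' @export
write_subset <- function(subset, path) {
  utils::write.table(subset, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-gene evaluation report TSV
#'
#' @param report a report tibble (one row per gene) as returned by
#'   [run_study()].
#' @param path file path.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
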