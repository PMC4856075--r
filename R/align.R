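# Best-stratum ungapped alignment with at most three mismatches, plus the
# length-dependent mismatch filter.
#
# Contract: for each read, report every placement (both strands) whose
# Hamming distance to the genome equals the minimum achievable distance d*,
# provided d* <= max_mismatches; nothing otherwise. A two-tier search is
# used: a hashed exact-window lookup resolves the 0-mismatch stratum, and a
# Biostrings scan handles reads with no exact placement. Both tiers satisfy
# the exhaustive-scan oracle exactly.

#' Build a genome index for alignment
#'
#' @param genome an `srna_genome`, a named character vector of chromosome
#'   sequences, or a path to a FASTA file.
#' @return object of class `genome_index`.
#' @export
genome_index <- function(genome) {
  seqs <- if (inherits(genome, "srna_genome")) {
    genome$seqs
  } else if (is.character(genome) && length(genome) == 1L &&
             file.exists(genome)) {
    x <- Biostrings::readDNAStringSet(genome)
    setNames(as.character(x), sub(" .*", "", names(x)))
  } else if (is.character(genome)) {
    stopifnot_named(genome, "genome sequences")
    genome
  } else stop("unsupported genome input", call. = FALSE)
  check_dna(unname(seqs), "genome")
  structure(list(seqs = seqs,
                 subject = Biostrings::DNAStringSet(seqs),
                 rc = Biostrings::reverseComplement(
                   Biostrings::DNAStringSet(seqs)),
                 cache = new.env(parent = emptyenv())),
            class = "genome_index")
}

# all genomic windows of length L on both strands, keyed by sequence
.window_table <- function(index, L) {
  key <- as.character(L)
  if (!is.null(index$cache[[key]])) return(index$cache[[key]])
  tabs <- lapply(names(index$seqs), function(ch) {
    s <- index$seqs[[ch]]
    n <- nchar(s)
    if (n < L) return(NULL)
    starts <- seq_len(n - L + 1L)
    fwd <- data.table(window = substring(s, starts, starts + L - 1L),
                      chrom = ch, start0 = starts - 1L, strand = "+")
    rcs <- as.character(index$rc[[match(ch, names(index$seqs))]])
    rev <- data.table(window = substring(rcs, starts, starts + L - 1L),
                      chrom = ch, start0 = n - starts - L + 1L, strand = "-")
    rbind(fwd, rev)
  })
  tab <- rbindlist(tabs)
  setkey(tab, window)
  index$cache[[key]] <- tab
  tab
}

# mismatch-tolerant scan for sequences with no exact placement
.scan_mm <- function(index, seq, max_mm) {
  pat <- Biostrings::DNAString(seq)
  rcp <- Biostrings::reverseComplement(pat)
  hits <- list()
  for (ci in seq_along(index$seqs)) {
    ch <- names(index$seqs)[ci]
    for (str in c("+", "-")) {
      p <- if (str == "+") pat else rcp
      m <- Biostrings::matchPattern(p, index$subject[[ci]],
                                    max.mismatch = max_mm,
                                    with.indels = FALSE)
      if (!length(m)) next
      starts <- Biostrings::start(m)
      mm <- Biostrings::neditStartingAt(p, index$subject[[ci]],
                                        starting.at = starts)
      hits[[length(hits) + 1L]] <-
        data.table(chrom = ch, start0 = starts - 1L, strand = str, mm = mm)
    }
  }
  if (!length(hits)) return(NULL)
  rbindlist(hits)
}

#' Align sequences under the best-stratum contract
#'
#' @param seqs character vector of read sequences (length >= 16 each is the
#'   intended use; shorter sequences are aligned as given).
#' @param index a [genome_index()].
#' @param max_mismatches maximum mismatches considered (default 3).
#' @return data.table with columns `sequence`, `chrom`, `start0` (0-based),
#'   `end0` (exclusive), `strand`, `mm`, ordered by (sequence input order,
#'   chrom, start0, strand). Sequences with no placement at d* <=
#'   `max_mismatches` are absent.
#' @export
align_sequences <- function(seqs, index, max_mismatches = 3L) {
  stopifnot(inherits(index, "genome_index"))
  check_dna(seqs, "read")
  uni <- unique(seqs)
  blocks <- list()
  by_len <- split(seq_along(uni), nchar(uni))
  for (L in names(by_len)) {
    ii <- by_len[[L]]
    wt <- .window_table(index, as.integer(L))
    ex <- wt[data.table(window = uni[ii]), on = "window", nomatch = NULL]
    found <- unique(ex$window)
    if (nrow(ex)) {
      blocks[[length(blocks) + 1L]] <-
        ex[, .(sequence = window, chrom, start0, strand, mm = 0L)]
    }
    for (k in ii[!(uni[ii] %in% found)]) {
      h <- .scan_mm(index, uni[k], max_mismatches)
      if (is.null(h)) next
      h <- h[mm == min(mm)]
      blocks[[length(blocks) + 1L]] <- data.table(sequence = uni[k], h)
    }
  }
  out <- rbindlist(blocks)
  if (!nrow(out)) {
    return(data.table(sequence = character(), chrom = character(),
                      start0 = integer(), end0 = integer(),
                      strand = character(), mm = integer()))
  }
  out[, end0 := start0 + nchar(sequence)]
  out[, seq_ord := match(sequence, uni)]
  setorder(out, seq_ord, chrom, start0, strand)
  out[, seq_ord := NULL]
  setcolorder(out, c("sequence", "chrom", "start0", "end0", "strand", "mm"))
  out[]
}

#' Align a single read
#'
#' @inheritParams align_sequences
#' @param sequence one read sequence.
#' @return data.table of best-stratum alignments (possibly empty).
#' @export
align_read <- function(sequence, index, max_mismatches = 3L) {
  stopifnot(length(sequence) == 1L)
  align_sequences(sequence, index, max_mismatches)
}

#' Length-dependent mismatch allowance
#'
#' The bins are 16-17 nt: 0 mismatches, 18-19 nt: 1, 20-24 nt: 2,
#' 25 nt and longer: 3.
#'
#' @return an object of class `length_mismatch_rule`.
#' @export
length_mismatch_rule <- function() {
  structure(list(breaks = c(16L, 18L, 20L, 25L), allowed = c(0L, 1L, 2L, 3L)),
            class = "length_mismatch_rule")
}

#' Maximum mismatches allowed for given read lengths
#' @param lengths integer vector of read lengths (>= 16).
#' @param rule a [length_mismatch_rule()].
#' @return integer vector of allowances.
#' @export
mismatch_allowance <- function(lengths, rule = length_mismatch_rule()) {
  if (any(lengths < min(rule$breaks)))
    stop("read shorter than 16 nt reached the mismatch filter; ",
         "apply the length filter upstream", call. = FALSE)
  rule$allowed[findInterval(lengths, rule$breaks)]
}

#' Apply the length-dependent mismatch filter
#'
#' @param alignments data.table from [align_sequences()] (columns `sequence`
#'   and `mm` required).
#' @param rule a [length_mismatch_rule()].
#' @return the alignments with logical column `accept` and a `reason`
#'   string for rejections.
#' @export
length_mismatch_filter <- function(alignments, rule = length_mismatch_rule()) {
  out <- copy(as.data.table(alignments))
  allowed <- mismatch_allowance(nchar(out$sequence), rule)
  out[, accept := mm <= allowed]
  out[, reason := ifelse(accept, NA_character_,
                         sprintf("length %d allows %d mismatches, found %d",
                                 nchar(sequence), allowed, mm))]
  out[]
}

#' Align a collapsed library and summarise mapping
#'
#' @param collapsed data.table with `sequence`, `count` ([collapse_reads()]).
#' @param index a [genome_index()].
#' @param max_mismatches best-stratum bound (default 3).
#' @param rule a [length_mismatch_rule()]; the filter is applied to the
#'   members of the already-computed best stratum.
#' @return list with `alignments` (surviving alignments with `count` and
#'   `n_best`, the read's surviving multiplicity) and `summary`
#'   (total_reads, mapped_reads, mapped_fraction).
#' @export
align_library <- function(collapsed, index, max_mismatches = 3L,
                          rule = length_mismatch_rule()) {
  aln <- align_sequences(collapsed$sequence, index, max_mismatches)
  total <- sum(collapsed$count)
  if (nrow(aln)) {
    aln <- length_mismatch_filter(aln, rule)[accept == TRUE]
    aln[, c("accept", "reason") := NULL]
    aln[, n_best := .N, by = sequence]
    aln <- merge(aln, as.data.table(collapsed)[, .(sequence, count)],
                 by = "sequence", sort = FALSE)
  } else {
    aln[, `:=`(n_best = integer(), count = integer())]
  }
  mapped <- if (nrow(aln)) sum(unique(aln, by = "sequence")$count) else 0L
  list(alignments = aln[],
       summary = data.table(total_reads = total, mapped_reads = mapped,
                            mapped_fraction = if (total > 0) mapped / total
                                              else NA_real_))
}

#' Write alignments as SAM
#'
#' Minimal single-end SAM with NM tags; 1-based POS per the SAM standard.
#'
#' @param alignments data.table from [align_library()] or
#'   [align_sequences()].
#' @param index the [genome_index()] used (for header lengths).
#' @param path output path.
#' @export
write_sam <- function(alignments, index, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(index$seqs),
                   nchar(index$seqs)))
  a <- as.data.table(alignments)
  seqout <- ifelse(a$strand == "-", revcomp(a$sequence), a$sequence)
  recs <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                  a$sequence, ifelse(a$strand == "-", 16L, 0L), a$chrom,
                  a$start0 + 1L, nchar(a$sequence), seqout, a$mm)
  writeLines(c(hdr, recs), path)
  invisible(path)
}
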