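# Adapter trimming, barcode demultiplexing, minimum-length filtering and
# collapsing of identical reads.
#
# Adapter-match contract: an adapter segment of length L matches with at
# most floor(error_rate * L) errors (substitutions + indels); the best match
# has the fewest errors, then the longest matched segment, then the leftmost
# start. The 3' adapter may be truncated at the read end (>= min_overlap
# bases); the 5' leader must match at the read start. N never matches.

#' Trimming specification
#'
#' @param adapter_3p 3' adapter; it and everything after it are removed.
#' @param adapter_5p 5' leader removed from the read start when present
#'   (empty string disables 5' trimming).
#' @param error_rate allowed errors per matched adapter base (default 0.25).
#' @param min_length minimum insert length kept downstream (default 16).
#' @param min_overlap minimum 3' adapter overlap at the read end (default 3).
#' @return object of class `trim_spec`.
#' @export
trim_spec <- function(adapter_3p = .default_adapter_3p,
                      adapter_5p = "",
                      error_rate = 0.25, min_length = 16L,
                      min_overlap = 3L) {
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 1)
    stop("error_rate must be in [0, 1)", call. = FALSE)
  if (!is_count(min_length) || min_length < 1L)
    stop("min_length must be >= 1", call. = FALSE)
  check_dna(adapter_3p, "adapter_3p", allow_n = FALSE)
  if (nzchar(adapter_5p)) check_dna(adapter_5p, "adapter_5p", allow_n = FALSE)
  structure(list(adapter_3p = adapter_3p, adapter_5p = adapter_5p,
                 error_rate = error_rate, min_length = as.integer(min_length),
                 min_overlap = as.integer(min_overlap)),
            class = "trim_spec")
}

# Semiglobal DP of `adapter` against `read`: free start anywhere in the read.
# Returns all candidate matches (end-anchored truncations included) as a
# data.frame(start, end, matched_len, errors); NULL if none pass the
# error allowance.
.adapter_dp <- function(read, adapter, error_rate, min_overlap) {
  r <- strsplit(read, "")[[1L]]; a <- strsplit(adapter, "")[[1L]]
  lr <- length(r); la <- length(a)
  # dp[j+1, i+1]: min errors aligning adapter[1..j] ending at read pos i,
  # start free; st tracks the read start (1-based) of that alignment
  dp <- matrix(0L, la + 1L, lr + 1L)
  st <- matrix(0L, la + 1L, lr + 1L)
  dp[, 1L] <- 0:la
  st[1L, ] <- 1:(lr + 1L)   # empty adapter "starts" right after pos i
  st[, 1L] <- 1L
  for (j in 1:la) {
    for (i in 1:lr) {
      sub <- dp[j, i] + (a[j] != r[i] || a[j] == "N" || r[i] == "N")
      del <- dp[j, i + 1L] + 1L       # adapter base unmatched
      ins <- dp[j + 1L, i] + 1L       # extra read base inside the match
      m <- min(sub, del, ins)
      dp[j + 1L, i + 1L] <- m
      st[j + 1L, i + 1L] <- if (m == sub) st[j, i] else {
        if (m == del) st[j, i + 1L] else st[j + 1L, i]
      }
    }
  }
  cand <- data.frame(start = st[la + 1L, 2:(lr + 1L)], end = 1:lr,
                     matched_len = la, errors = dp[la + 1L, 2:(lr + 1L)])
  if (min_overlap < la) {
    js <- min_overlap:(la - 1L)
    cand <- rbind(cand,
                  data.frame(start = st[js + 1L, lr + 1L], end = lr,
                             matched_len = js, errors = dp[js + 1L, lr + 1L]))
  }
  cand <- cand[cand$errors <= floor(error_rate * cand$matched_len), ,
               drop = FALSE]
  if (!nrow(cand)) return(NULL)
  # best = most matched bases, then fewest errors, then leftmost start
  # (a fewest-errors-first rule would let a short perfect end-overlap beat a
  # full adapter occurrence carrying allowed errors)
  cand[order(-(cand$matched_len - cand$errors), cand$errors, cand$start), ,
       drop = FALSE][1L, ]
}

# fast path: a full exact adapter occurrence is always the best candidate
# (maximal matched bases, zero errors, leftmost); anything else needs the DP
.exact_3p_start <- function(seqs, adapter, min_overlap) {
  pos <- regexpr(adapter, seqs, fixed = TRUE)
  ifelse(pos > 0L, as.integer(pos), NA_integer_)
}

#' Trim adapters from reads
#'
#' Vectorised over a character vector of read sequences. The exact-match
#' fast path handles full and end-truncated perfect adapter occurrences;
#' remaining reads go through a semiglobal alignment allowing
#' `floor(error_rate * matched_length)` substitutions + indels.
#'
#' @param seqs character vector of read sequences (A/C/G/T/N).
#' @param spec a [trim_spec()].
#' @return data.table with columns `sequence` (trimmed), `status` in
#'   `trimmed` / `untrimmed` / `empty`, and `input` (the original read).
#'   `empty` reads (nothing left after trimming) are the discard bin.
#' @export
trim_reads <- function(seqs, spec = trim_spec()) {
  check_dna(seqs, "read")
  out <- seqs
  status <- rep("untrimmed", length(seqs))

  if (nzchar(spec$adapter_5p)) {
    a5 <- spec$adapter_5p; la <- nchar(a5)
    allow <- floor(spec$error_rate * la)
    exact <- startsWith(out, a5)
    out[exact] <- substring(out[exact], la + 1L)
    need <- !exact & nchar(out) > 0L
    for (i in which(need)) {
      hit <- .leader_dp(out[i], a5, allow)
      if (!is.na(hit)) out[i] <- substring(out[i], hit + 1L)
      exact[i] <- !is.na(hit)
    }
    status[exact] <- "trimmed"
  }

  uni <- unique(out)
  start <- .exact_3p_start(uni, spec$adapter_3p, spec$min_overlap)
  todo <- which(is.na(start))
  for (i in todo) {
    hit <- .adapter_dp(uni[i], spec$adapter_3p, spec$error_rate,
                       spec$min_overlap)
    if (!is.null(hit)) start[i] <- hit$start
  }
  m <- match(out, uni)
  s <- start[m]
  has <- !is.na(s)
  out[has] <- substr(out[has], 1L, s[has] - 1L)
  status[has] <- "trimmed"
  status[nchar(out) == 0L] <- "empty"
  data.table(sequence = out, status = status, input = seqs)
}

# 5' leader: full adapter aligned starting at read position 1; returns the
# number of read bases consumed, or NA
.leader_dp <- function(read, adapter, allow) {
  r <- strsplit(read, "")[[1L]]; a <- strsplit(adapter, "")[[1L]]
  lr <- min(length(r), length(a) + allow); la <- length(a)
  dp <- matrix(0L, la + 1L, lr + 1L)
  dp[1L, ] <- 0:lr; dp[, 1L] <- 0:la
  for (j in 1:la) for (i in 1:lr) {
    dp[j + 1L, i + 1L] <- min(
      dp[j, i] + (a[j] != r[i] || a[j] == "N" || r[i] == "N"),
      dp[j, i + 1L] + 1L, dp[j + 1L, i] + 1L)
  }
  err <- min(dp[la + 1L, ])
  if (err > allow) return(NA_integer_)
  max(which(dp[la + 1L, ] == err)) - 1L
}

#' Trim a single read
#'
#' @param read a single read sequence.
#' @param spec a [trim_spec()].
#' @return list with `sequence`, `status` and `input`.
#' @export
trim_read <- function(read, spec = trim_spec()) {
  stopifnot(length(read) == 1L)
  as.list(trim_reads(read, spec)[1L])
}

#' Demultiplex reads by exact barcode prefix
#'
#' A read is assigned to a library iff its prefix equals that library's
#' barcode exactly; the barcode is stripped on assignment. Everything else
#' lands in the `undetermined` bin.
#'
#' @param seqs character vector of (trimmed) read sequences.
#' @param barcode_map named character vector: library name -> barcode.
#' @return list with `libraries` (named list of character vectors) and
#'   `undetermined` (character vector).
#' @export
demultiplex <- function(seqs, barcode_map) {
  stopifnot_named(barcode_map, "barcode_map")
  if (anyDuplicated(barcode_map))
    stop("duplicate barcodes in map", call. = FALSE)
  if (length(unique(nchar(barcode_map))) > 1L)
    stop("barcodes must have equal length", call. = FALSE)
  bl <- nchar(barcode_map[[1L]])
  prefix <- substr(seqs, 1L, bl)
  lib <- names(barcode_map)[match(prefix, barcode_map)]
  assigned <- !is.na(lib)
  libs <- lapply(setNames(names(barcode_map), names(barcode_map)),
                 function(l) substring(seqs[assigned & lib == l], bl + 1L))
  list(libraries = libs, undetermined = seqs[!assigned])
}

#' Minimum-length filter
#'
#' @param seqs character vector of sequences.
#' @param min_length reads shorter than this are removed (default 16).
#' @return list with `kept` and `removed` character vectors.
#' @export
length_filter <- function(seqs, min_length = 16L) {
  if (!is_count(min_length) || min_length < 1L)
    stop("min_length must be >= 1", call. = FALSE)
  keep <- nchar(seqs) >= min_length
  list(kept = seqs[keep], removed = seqs[!keep])
}

#' Collapse identical reads into counted unique sequences
#'
#' @param seqs character vector of reads from one library.
#' @param library library identifier stored on the result.
#' @return data.table with columns `sequence`, `count`, ordered by
#'   decreasing count then sequence; attribute `library`.
#' @export
collapse_reads <- function(seqs, library = NA_character_) {
  dt <- data.table(sequence = seqs)[, .(count = .N), by = sequence]
  setorder(dt, -count, sequence)
  setattr(dt, "library", library)
  dt[]
}

#' Write collapsed reads as a counted FASTA
#'
#' Headers follow the `>seq<rank>_x<count>` convention.
#'
#' @param collapsed data.table from [collapse_reads()].
#' @param path output FASTA path.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  hdr <- sprintf(">seq%d_x%d", seq_len(nrow(collapsed)), collapsed$count)
  writeLines(as.vector(rbind(hdr, collapsed$sequence)), path)
  invisible(path)
}

#' Read a counted FASTA back
#' @param path FASTA path as written by [write_collapsed_fasta()].
#' @return data.table with `sequence`, `count`.
#' @export
read_collapsed_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.table(sequence = as.character(unname(x)),
             count = as.integer(sub(".*_x", "", names(x))))
}

#' Full preprocessing of one FASTQ into per-library collapsed reads
#'
#' trim -> demultiplex -> length filter -> collapse, with a conservation
#' summary: every input read is exactly one of assigned, undetermined,
#' discarded-short or discarded-empty.
#'
#' @param seqs character vector of raw read sequences (or a data.table with
#'   a `sequence` column as returned by [read_fastq()]).
#' @param barcode_map named character vector: library -> barcode.
#' @param spec a [trim_spec()].
#' @param keep_untrimmed keep reads in which no adapter was found
#'   (default TRUE).
#' @return list with `collapsed` (named list of collapsed-read tables),
#'   `summary` (data.table of per-bin read counts) and `undetermined`.
#' @export
preprocess_reads <- function(seqs, barcode_map, spec = trim_spec(),
                             keep_untrimmed = TRUE) {
  if (is.data.frame(seqs)) seqs <- seqs$sequence
  tr <- trim_reads(seqs, spec)
  n_empty <- sum(tr$status == "empty")
  keep <- tr$status == "trimmed" | (keep_untrimmed & tr$status == "untrimmed")
  n_untrimmed_drop <- sum(!keep) - n_empty
  dm <- demultiplex(tr$sequence[keep & tr$status != "empty"], barcode_map)
  collapsed <- list(); n_short <- 0L; n_assigned <- 0L
  for (lib in names(dm$libraries)) {
    lf <- length_filter(dm$libraries[[lib]], spec$min_length)
    n_short <- n_short + length(lf$removed)
    n_assigned <- n_assigned + length(lf$kept)
    collapsed[[lib]] <- collapse_reads(lf$kept, lib)
  }
  summary <- data.table(
    bin = c("input", "assigned", "undetermined", "discarded_short",
            "discarded_empty", "discarded_untrimmed"),
    reads = c(length(seqs), n_assigned, length(dm$undetermined), n_short,
              n_empty, max(n_untrimmed_drop, 0L)))
  list(collapsed = collapsed, summary = summary,
       undetermined = dm$undetermined)
}
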