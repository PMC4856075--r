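# Simulated small RNA libraries: barcoded, 3'-adapter-ligated reads drawn
# from an annotated toy genome with per-read ground truth and optional
# between-condition fold-change spikes.

# 3' sequencing adapter and 5' leader used in the emulated cloning chemistry
.default_adapter_3p <- "GATCGTTCGGACTGTAGATC"
.default_adapter_5p <- "ATTGATGGTGCCTACAG"

.sim_classes <- c("mirna", "endo_sirna", "pirna", "trna", "rrna",
                  "transposon", "gene_sense", "intergenic")

#' Default insert length distributions per small RNA class
#'
#' Probabilities over insert lengths inside the 18-26 nt gel-selection
#' window: miRNAs peak at 22 nt, piRNAs are exactly 21 nt, endogenous
#' siRNAs (and transposon-derived reads) peak at 22 nt, and structural-RNA
#' fragments are broad.
#'
#' @return named list of named probability vectors (names are lengths).
#' @export
default_length_dists <- function() {
  norm <- function(x) x / sum(x)
  broad <- setNames(rep(1, 9), 18:26)
  list(
    mirna      = norm(setNames(c(0.10, 0.20, 0.50, 0.15, 0.05), 20:24)),
    pirna      = setNames(1, 21),
    endo_sirna = norm(setNames(c(0.10, 0.15, 0.60, 0.15), 20:23)),
    transposon = norm(setNames(c(0.10, 0.15, 0.60, 0.15), 20:23)),
    trna       = norm(broad),
    rrna       = norm(broad),
    gene_sense = norm(broad),
    intergenic = norm(broad)
  )
}

#' Generate mutually distant barcodes
#'
#' Deterministically enumerates DNA words of the given width and greedily
#' keeps words at pairwise Hamming distance of at least `min_dist`.
#'
#' @param n number of barcodes.
#' @param width barcode length (default 4).
#' @param min_dist minimum pairwise Hamming distance (default 2).
#' @return character vector of `n` barcodes.
#' @export
make_barcodes <- function(n, width = 4L, min_dist = 2L) {
  bases <- c("A", "C", "G", "T")
  all <- do.call(paste0, rev(expand.grid(rep(list(bases), width),
                                         stringsAsFactors = FALSE)))
  hamming <- function(a, b)
    sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  out <- character(0)
  for (w in all) {
    if (all(vapply(out, hamming, 0L, b = w) >= min_dist)) out <- c(out, w)
    if (length(out) == n) return(out)
  }
  stop(sprintf("cannot generate %d barcodes of width %d at distance >= %d",
               n, width, min_dist), call. = FALSE)
}

#' Specification of a simulated small RNA experiment
#'
#' Defaults emulate the structure of a two-genotype worm experiment: three
#' replicate libraries per group, reads built as
#' `barcode + insert + 3' adapter` (truncated at the read end), class
#' proportions dominated by miRNAs with a substantial antisense endo-siRNA
#' fraction, and inserts confined to the 18-26 nt gel window.
#'
#' @param n_libraries_per_group replicates per group (default 3).
#' @param reads_per_library reads per library (default 50000).
#' @param class_proportions named numeric vector over the classes
#'   `r paste(.sim_classes, collapse = ", ")`; must sum to 1.
#' @param insert_length_distributions per-class length distributions, as
#'   [default_length_dists()].
#' @param adapter_3p 3' adapter sequence ligated after the insert.
#' @param adapter_5p_leader optional 5' leader placed before the barcode
#'   (default empty).
#' @param barcode_map named character vector, library name to barcode; by
#'   default generated with [make_barcodes()] for libraries
#'   `wt_1..wt_k, mut_1..mut_k`.
#' @param error_rate per-base substitution probability (default 0.001).
#' @param spike_table data.frame with columns `feature_id`, `fold_change`
#'   (> 0); mutant-group abundances of these features are scaled.
#' @param mirna_offset_probs named probability vector over 5' offsets of
#'   miRNA read starts relative to the annotated mature 5' end.
#' @param max_read_length sequencer read length; read strings are truncated
#'   here, which truncates the 3' adapter when barcode + insert + adapter
#'   exceed it (default 50).
#' @param seed integer seed.
#' @return object of class `library_spec`.
#' @export
library_spec <- function(n_libraries_per_group = 3L,
                         reads_per_library = 50000L,
                         class_proportions = c(
                           mirna = 0.45, endo_sirna = 0.25, pirna = 0.08,
                           trna = 0.08, rrna = 0.06, transposon = 0.04,
                           gene_sense = 0.02, intergenic = 0.02),
                         insert_length_distributions = default_length_dists(),
                         adapter_3p = .default_adapter_3p,
                         adapter_5p_leader = "",
                         barcode_map = NULL,
                         error_rate = 0.001,
                         spike_table = NULL,
                         mirna_offset_probs = c(`-2` = 0.05, `-1` = 0.15,
                                                `0` = 0.60, `1` = 0.15,
                                                `2` = 0.05),
                         max_read_length = 50L,
                         seed = 1L) {
  stopifnot(is_count(n_libraries_per_group), n_libraries_per_group >= 1,
            is_count(reads_per_library))
  stopifnot_named(class_proportions, "class_proportions")
  if (!setequal(names(class_proportions), .sim_classes))
    stop("class_proportions must cover exactly the classes: ",
         paste(.sim_classes, collapse = ", "), call. = FALSE)
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class_proportions must sum to 1", call. = FALSE)
  if (any(class_proportions < 0)) stop("negative class proportion")
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 1)
    stop("error_rate must be in [0, 1)", call. = FALSE)
  check_dna(adapter_3p, "adapter_3p", allow_n = FALSE)
  if (!nzchar(adapter_3p)) stop("adapter_3p must be non-empty", call. = FALSE)
  if (is.null(barcode_map)) {
    k <- n_libraries_per_group
    libs <- c(sprintf("wt_%d", seq_len(k)), sprintf("mut_%d", seq_len(k)))
    barcode_map <- setNames(make_barcodes(2L * k), libs)
  }
  stopifnot_named(barcode_map, "barcode_map")
  if (anyDuplicated(barcode_map))
    stop("barcodes must be unique", call. = FALSE)
  if (length(unique(nchar(barcode_map))) != 1L)
    stop("barcodes must have equal length", call. = FALSE)
  if (!is.null(spike_table)) {
    spike_table <- as.data.frame(spike_table)
    stopifnot(all(c("feature_id", "fold_change") %in% names(spike_table)))
    if (any(spike_table$fold_change <= 0))
      stop("fold changes must be > 0", call. = FALSE)
  }
  for (cl in .sim_classes) {
    d <- insert_length_distributions[[cl]]
    if (is.null(d) || abs(sum(d) - 1) > 1e-8 ||
        any(as.integer(names(d)) < 16L | as.integer(names(d)) > 30L))
      stop(sprintf(
        "insert_length_distributions$%s must sum to 1 over lengths 16-30",
        cl), call. = FALSE)
  }
  if (abs(sum(mirna_offset_probs) - 1) > 1e-8)
    stop("mirna_offset_probs must sum to 1", call. = FALSE)
  structure(list(
    n_libraries_per_group = as.integer(n_libraries_per_group),
    reads_per_library = as.integer(reads_per_library),
    class_proportions = class_proportions,
    insert_length_distributions = insert_length_distributions,
    adapter_3p = adapter_3p, adapter_5p_leader = adapter_5p_leader,
    barcode_map = barcode_map, error_rate = error_rate,
    spike_table = spike_table, mirna_offset_probs = mirna_offset_probs,
    max_read_length = as.integer(max_read_length),
    seed = as.integer(seed)), class = "library_spec")
}

# per-feature sampling units: one row per (feature, class) drawable region set
.feature_weights <- function(genome) {
  ann <- genome$annotation
  ft <- ann$features
  units <- list()
  mir <- ft[class == "miRNA"]
  if (nrow(mir)) {
    units$mirna <- rbindlist(lapply(c("g", "p"), function(a)
      data.table(feature_id = paste0(mir$id, ":", a), class = "mirna",
                 locus = mir$id, arm = a,
                 arm_w = if (a == "g") 0.85 else 0.15)))
  }
  genes <- ft[class == "gene"]
  if (nrow(genes)) {
    units$endo_sirna <- data.table(feature_id = genes$id, class = "endo_sirna",
                                   locus = genes$id, arm = NA, arm_w = 1)
    units$gene_sense <- data.table(feature_id = genes$id, class = "gene_sense",
                                   locus = genes$id, arm = NA, arm_w = 1)
  }
  simple <- c(pirna = "piRNA_gene", trna = "tRNA", rrna = "rRNA",
              transposon = "transposable_element")
  for (cl in names(simple)) {
    f <- ft[class == simple[[cl]]]
    if (nrow(f))
      units[[cl]] <- data.table(feature_id = f$id, class = cl, locus = f$id,
                                arm = NA, arm_w = 1)
  }
  ig <- .intergenic_windows(genome)
  if (nrow(ig)) {
    units$intergenic <- data.table(
      feature_id = sprintf("ig:%s:%d", ig$chrom, ig$start0),
      class = "intergenic", locus = NA, arm = NA, arm_w = ig$end0 - ig$start0)
  }
  rbindlist(units, fill = TRUE)
}

# vectorised substring extraction on the sense strand of `strand`
.extract <- function(seqs, chrom, start0, len, strand) {
  fwd <- substring(seqs[chrom], start0 + 1L, start0 + len)
  out <- fwd
  neg <- strand == "-"
  if (any(neg)) out[neg] <- revcomp(fwd[neg])
  out
}

#' Simulate barcoded small RNA libraries with ground truth
#'
#' Draws `reads_per_library` reads per library from a multinomial over
#' sampling units (miRNA arms, genes, piRNA/tRNA/rRNA/transposon loci and
#' intergenic windows) whose weights combine the class proportions, a fixed
#' per-feature abundance skew and, for mutant libraries, the spike table.
#' Each read is `leader + barcode + insert + 3' adapter` truncated at
#' `max_read_length`, with substitution errors applied at `error_rate`.
#'
#' @param genome an `srna_genome` from [build_genome()].
#' @param spec a [library_spec()].
#' @return object of class `srna_experiment`: list with `reads` (named list
#'   of data.tables `id`, `sequence`, `quality`), `truth` (one row per read:
#'   library, read id, feature, class, genomic interval, read strand, miRNA
#'   5' offset, error-free insert), `groups`, `barcode_map`, `spec`.
#' @export
simulate_libraries <- function(genome, spec) {
  stopifnot(inherits(genome, "srna_genome"), inherits(spec, "library_spec"))
  ann <- genome$annotation
  if (!is.null(spec$spike_table)) {
    units0 <- .feature_weights(genome)
    miss <- setdiff(spec$spike_table$feature_id, units0$feature_id)
    if (length(miss))
      stop("spike_table references unknown features: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  libs <- names(spec$barcode_map)
  groups <- setNames(ifelse(grepl("^mut", libs), "mut", "wt"), libs)

  if (spec$reads_per_library == 0L) {
    warning("reads_per_library = 0: emitting empty libraries")
    empty <- data.table(id = character(), sequence = character(),
                        quality = character())
    return(structure(list(
      reads = setNames(rep(list(empty), length(libs)), libs),
      truth = data.table(library = character(), read_id = character(),
                         feature_id = character(), class = character(),
                         chrom = character(), start0 = integer(),
                         end0 = integer(), strand = character(),
                         offset5p = integer(), insert = character()),
      groups = groups, barcode_map = spec$barcode_map, spec = spec),
      class = "srna_experiment"))
  }

  with_seed(spec$seed, {
    units <- .feature_weights(genome)
    present <- intersect(.sim_classes, unique(units$class))
    absent_p <- sum(spec$class_proportions[setdiff(.sim_classes, present)])
    if (absent_p > 0)
      stop("class_proportions assigns mass to classes with no features: ",
           paste(setdiff(.sim_classes, present)[
             spec$class_proportions[setdiff(.sim_classes, present)] > 0],
             collapse = ", "), call. = FALSE)
    # fixed per-feature abundance skew, shared by all libraries
    units[, skew := exp(stats::rnorm(.N, 0, 1)) * arm_w]
    units[, base_w := spec$class_proportions[class] * skew / sum(skew),
          by = class]
    units[, fold := 1]
    if (!is.null(spec$spike_table)) {
      st <- as.data.table(spec$spike_table)
      units[st, fold := i.fold_change, on = "feature_id"]
    }

    ig <- .intergenic_windows(genome)
    reads <- list(); truths <- list()
    for (lib in libs) {
      w <- units$base_w * (if (groups[[lib]] == "mut") units$fold else 1)
      n <- spec$reads_per_library
      pick <- sample.int(nrow(units), n, replace = TRUE, prob = w)
      tr <- .draw_inserts(genome, ann, ig, units[pick], spec)
      tr[, `:=`(library = lib,
                read_id = sprintf("%s_r%07d", lib, seq_len(n)))]
      raw <- paste0(spec$adapter_5p_leader, spec$barcode_map[[lib]],
                    tr$insert, spec$adapter_3p)
      raw <- substr(raw, 1L, spec$max_read_length)
      if (spec$error_rate > 0) raw <- .apply_errors(raw, spec$error_rate)
      reads[[lib]] <- data.table(id = tr$read_id, sequence = raw,
                                 quality = strrep("I", nchar(raw)))
      truths[[lib]] <- tr
    }
    truth <- rbindlist(truths)[
      , .(library, read_id, feature_id, class, chrom, start0, end0, strand,
          offset5p, insert)]
    structure(list(reads = reads, truth = truth, groups = groups,
                   barcode_map = spec$barcode_map, spec = spec),
              class = "srna_experiment")
  })
}

# draw one insert per row of `picked` (a row-expanded slice of the unit table)
.draw_inserts <- function(genome, ann, ig, picked, spec) {
  seqs <- genome$seqs
  n <- nrow(picked)
  out <- data.table(feature_id = picked$feature_id, class = picked$class,
                    chrom = NA_character_, start0 = NA_integer_,
                    end0 = NA_integer_, strand = NA_character_,
                    offset5p = NA_integer_, insert = NA_character_)
  draw_len <- function(cl, k) {
    d <- spec$insert_length_distributions[[cl]]
    as.integer(sample(as.integer(names(d)), k, replace = TRUE, prob = d))
  }
  ft <- ann$features

  idx <- which(picked$class == "mirna")
  if (length(idx)) {
    key <- data.table(mirna_id = picked$locus[idx], arm = picked$arm[idx])
    m <- ann$mature[key, on = c("mirna_id", "arm")]
    off <- as.integer(sample(as.integer(names(spec$mirna_offset_probs)),
                             length(idx), replace = TRUE,
                             prob = spec$mirna_offset_probs))
    len <- draw_len("mirna", length(idx))
    pos5 <- ifelse(m$strand == "+", m$mature_5p_position0 + off,
                   m$mature_5p_position0 - off)
    s0 <- as.integer(ifelse(m$strand == "+", pos5, pos5 - len + 1L))
    out[idx, `:=`(chrom = m$chrom, start0 = s0, end0 = s0 + len,
                  strand = m$strand, offset5p = off,
                  insert = .extract(seqs, m$chrom, s0, len, m$strand))]
  }

  idx <- which(picked$class == "pirna")
  if (length(idx)) {
    f <- ft[picked$locus[idx], on = "id"]
    len <- 21L
    s0 <- as.integer(ifelse(f$strand == "+", f$start0, f$end0 - len))
    out[idx, `:=`(chrom = f$chrom, start0 = s0, end0 = s0 + len,
                  strand = f$strand,
                  insert = .extract(seqs, f$chrom, s0, len, f$strand))]
  }

  for (cl in c("trna", "rrna")) {
    idx <- which(picked$class == cl)
    if (!length(idx)) next
    f <- ft[picked$locus[idx], on = "id"]
    len <- pmin(draw_len(cl, length(idx)), f$end0 - f$start0)
    s0 <- f$start0 +
      as.integer(floor(runif(length(idx)) * (f$end0 - f$start0 - len + 1L)))
    out[idx, `:=`(chrom = f$chrom, start0 = s0, end0 = s0 + len,
                  strand = f$strand,
                  insert = .extract(seqs, f$chrom, s0, len, f$strand))]
  }

  # antisense classes: read strand opposite the locus strand, 5' G preferred
  for (cl in c("endo_sirna", "transposon")) {
    idx <- which(picked$class == cl)
    if (!length(idx)) next
    if (cl == "endo_sirna") {
      regions <- ft[class %in% c("five_prime_UTR", "exon", "three_prime_UTR")]
      f <- .pick_subregion(regions, picked$locus[idx])
    } else {
      f <- ft[picked$locus[idx], on = "id"]
    }
    len <- draw_len(cl, length(idx))
    read_strand <- ifelse(f$strand == "+", "-", "+")
    s0 <- .sample_start_5pG(seqs, f, len, read_strand)
    out[idx, `:=`(chrom = f$chrom, start0 = s0, end0 = s0 + len,
                  strand = read_strand,
                  insert = .extract(seqs, f$chrom, s0, len, read_strand))]
  }

  idx <- which(picked$class == "gene_sense")
  if (length(idx)) {
    regions <- ft[class %in% c("five_prime_UTR", "exon", "three_prime_UTR")]
    f <- .pick_subregion(regions, picked$locus[idx])
    len <- draw_len("gene_sense", length(idx))
    s0 <- f$start0 +
      as.integer(floor(runif(length(idx)) * (f$end0 - f$start0 - len + 1L)))
    out[idx, `:=`(chrom = f$chrom, start0 = s0, end0 = s0 + len,
                  strand = f$strand,
                  insert = .extract(seqs, f$chrom, s0, len, f$strand))]
  }

  idx <- which(picked$class == "intergenic")
  if (length(idx)) {
    key <- data.table(fid = picked$feature_id[idx])
    igk <- copy(ig)[, fid := sprintf("ig:%s:%d", chrom, start0)]
    f <- igk[key, on = "fid"]
    len <- draw_len("intergenic", length(idx))
    s0 <- f$start0 +
      as.integer(floor(runif(length(idx)) * (f$end0 - f$start0 - len + 1L)))
    str <- sample(c("+", "-"), length(idx), replace = TRUE)
    out[idx, `:=`(chrom = f$chrom, start0 = s0, end0 = s0 + len,
                  strand = str,
                  insert = .extract(seqs, f$chrom, s0, len, str))]
  }
  out
}

# choose a gene sub-region proportionally to its width, one per request
.pick_subregion <- function(regions, gene_ids) {
  by_gene <- split(seq_len(nrow(regions)), regions$parent)
  rows <- integer(length(gene_ids))
  for (g in unique(gene_ids)) {
    ii <- which(gene_ids == g)
    cand <- by_gene[[g]]
    if (is.null(cand)) stop("gene without sub-features: ", g, call. = FALSE)
    w <- regions$end0[cand] - regions$start0[cand]
    rows[ii] <- cand[sample.int(length(cand), length(ii), replace = TRUE,
                                prob = w)]
  }
  regions[rows]
}

# rejection-sample window starts so the read 5' base is G where possible
.sample_start_5pG <- function(seqs, f, len, read_strand) {
  n <- nrow(f)
  s0 <- integer(n); need <- rep(TRUE, n)
  for (round in 1:12) {
    k <- which(need)
    if (!length(k)) break
    cand <- f$start0[k] +
      as.integer(floor(runif(length(k)) *
                         (f$end0[k] - f$start0[k] - len[k] + 1L)))
    s0[k] <- cand
    pos5 <- ifelse(read_strand[k] == "+", cand + 1L, cand + len[k])
    base <- substring(seqs[f$chrom[k]], pos5, pos5)
    ok <- ifelse(read_strand[k] == "+", base == "G", base == "C")
    need[k] <- !ok
  }
  s0
}

# per-base substitution errors; slow path only touches reads with errors
.apply_errors <- function(reads, rate) {
  nerr <- stats::rbinom(length(reads), nchar(reads), rate)
  hit <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    s <- strsplit(reads[i], "")[[1L]]
    pos <- sample.int(length(s), nerr[i])
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

#' @export
print.srna_experiment <- function(x, ...) {
  cat(sprintf("srna_experiment: %d libraries x %s reads\n",
              length(x$reads),
              paste(unique(vapply(x$reads, nrow, 0L)), collapse = "/")))
  invisible(x)
}

#' Write reads as FASTQ
#'
#' @param reads data.table with columns `id`, `sequence`, `quality` (one
#'   element of `srna_experiment$reads`).
#' @param path output path; written gzip-compressed if it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- if (nrow(reads) == 0L) character(0) else {
    as.vector(rbind(paste0("@", reads$id), reads$sequence, "+",
                    reads$quality))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file, optionally gzipped.
#' @return data.table with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: line count not a multiple of 4", call. = FALSE)
  if (!length(lines))
    return(data.table(id = character(), sequence = character(),
                      quality = character()))
  i <- seq(1L, length(lines), by = 4L)
  data.table(id = sub("^@", "", sub(" .*", "", lines[i])),
             sequence = lines[i + 1L], quality = lines[i + 3L])
}

#' Write ground truth as TSV
#' @param experiment an `srna_experiment`.
#' @param path output TSV path.
#' @export
write_ground_truth <- function(experiment, path) {
  fwrite(experiment$truth, path, sep = "\t")
  invisible(path)
}
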