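# Assignment of filtered alignments to annotation categories: miRNAs via a
# +/-5 nt window around annotated mature 5' ends (sense only), all other
# features by full containment with sense/antisense orientation recorded
# separately, endo-siRNAs as reads antisense to 5'UTR/exon/3'UTR gene
# sub-regions, and a precedence rule for the single-label read summary.

.class_labels <- c("miRNA", "rRNA_sense", "rRNA_antisense", "tRNA_sense",
                   "tRNA_antisense", "piRNA", "transposon_sense",
                   "transposon_antisense", "endo_siRNA", "gene_sense",
                   "unannotated")

# class precedence for the single-label summary (higher wins); orientation
# sense beats antisense within a class
.precedence <- c(miRNA = 8, rRNA = 7, tRNA = 6, piRNA = 5, transposon = 4,
                 endo_siRNA = 3, gene_sense = 2, unannotated = 0)

#' Assign alignments to mature miRNAs via the 5'-end window
#'
#' An alignment is assigned to a mature arm iff it lies on the arm's strand
#' and its 5' end (`start0` on `+`, `end0 - 1` on `-`) falls within
#' `window` nt of the annotated mature 5' position. Ties across overlapping
#' arms go to the nearest anchor, then guide over passenger, then id.
#'
#' @param alignments data.table with `chrom`, `start0`, `end0`, `strand`.
#' @param mature mature-miRNA table (`annotation_set$mature`).
#' @param window half-width of the acceptance window in nt (default 5).
#' @return character vector, one element per alignment row: the arm id
#'   `"<mirna_id>:<arm>"` or `NA`.
#' @export
assign_mirna <- function(alignments, mature, window = 5L) {
  aln <- as.data.table(alignments)
  out <- rep(NA_character_, nrow(aln))
  if (!nrow(aln) || !nrow(mature)) return(out)
  aln[, `:=`(.row = .I, pos5 = ifelse(strand == "+", start0, end0 - 1L))]
  m <- merge(aln[, .(.row, chrom, strand, pos5)],
             as.data.table(mature), by = c("chrom", "strand"),
             allow.cartesian = TRUE)
  m <- m[abs(pos5 - mature_5p_position0) <= window]
  if (!nrow(m)) return(out)
  m[, dist := abs(pos5 - mature_5p_position0)]
  setorder(m, .row, dist, arm, mirna_id)
  m <- m[!duplicated(.row)]
  out[m$.row] <- paste0(m$mirna_id, ":", m$arm)
  out
}

#' Report features fully containing each alignment
#'
#' A feature is reported iff the alignment interval lies entirely within the
#' feature interval; orientation is `sense` iff the strands match. Gene
#' sub-regions (5'UTR/exon/3'UTR) are reported with their parent gene id.
#'
#' @param alignments data.table with `chrom`, `start0`, `end0`, `strand`.
#' @param annotation an [annotation_set()].
#' @return data.table with columns `aln_row` (row in `alignments`),
#'   `feature_id`, `class`, `gene_id` (parent gene for sub-regions),
#'   `subregion`, `orientation`.
#' @export
assign_features <- function(alignments, annotation) {
  aln <- as.data.table(alignments)
  cls <- c("piRNA_gene", "tRNA", "rRNA", "transposable_element",
           "five_prime_UTR", "exon", "three_prime_UTR")
  ft <- annotation$features[class %in% cls]
  if (!nrow(aln) || !nrow(ft)) {
    return(data.table(aln_row = integer(), feature_id = character(),
                      class = character(), gene_id = character(),
                      subregion = character(), orientation = character()))
  }
  q <- GenomicRanges::GRanges(aln$chrom,
                              IRanges::IRanges(aln$start0 + 1L, aln$end0))
  s <- GenomicRanges::GRanges(ft$chrom,
                              IRanges::IRanges(ft$start0 + 1L, ft$end0))
  ov <- GenomicRanges::findOverlaps(q, s, type = "within",
                                    ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  sub <- ft$class[si] %in% c("five_prime_UTR", "exon", "three_prime_UTR")
  data.table(
    aln_row = qi,
    feature_id = ifelse(sub, ft$parent[si], ft$id[si]),
    class = ifelse(sub, "gene", ft$class[si]),
    gene_id = ifelse(sub, ft$parent[si], NA_character_),
    subregion = ifelse(sub, ft$class[si], NA_character_),
    orientation = ifelse(aln$strand[qi] == ft$strand[si], "sense",
                         "antisense"))
}

# annotate every alignment row of a library; weights follow the
# multi-mapper policy: fractional = count / n_best per alignment
.annotate_alignments <- function(alignments, annotation, window = 5L,
                                 count_mode = c("fractional", "all")) {
  count_mode <- match.arg(count_mode)
  aln <- as.data.table(alignments)
  if (!("n_best" %in% names(aln))) aln[, n_best := 1L]
  if (!("count" %in% names(aln))) aln[, count := 1L]
  aln[, aln_row := .I]
  aln[, weight := if (count_mode == "fractional") count / n_best
                  else as.numeric(count)]
  aln[, mirna := assign_mirna(aln, annotation$mature, window)]
  hits <- assign_features(aln, annotation)
  list(aln = aln, hits = hits)
}

#' Classify reads into single class labels
#'
#' Applies the precedence miRNA > rRNA > tRNA > piRNA (sense) > transposon >
#' gene-antisense (endo-siRNA) > gene-sense > unannotated across all
#' surviving alignments of each read; within a class, sense beats antisense.
#'
#' @param alignments surviving alignments of one library
#'   (`align_library()$alignments`).
#' @param annotation an [annotation_set()].
#' @param window miRNA 5'-end window (default 5).
#' @return data.table with one row per distinct read sequence: `sequence`,
#'   `count`, `label`.
#' @export
classify_reads <- function(alignments, annotation, window = 5L) {
  ann <- .annotate_alignments(alignments, annotation, window)
  aln <- ann$aln; hits <- ann$hits
  cand <- rbind(
    aln[!is.na(mirna), .(aln_row, class = "miRNA", orientation = "sense")],
    hits[class == "piRNA_gene" & orientation == "sense",
         .(aln_row, class = "piRNA", orientation)],
    hits[class %in% c("tRNA", "rRNA", "transposable_element"),
         .(aln_row, class = sub("transposable_element", "transposon", class),
           orientation)],
    hits[class == "gene",
         .(aln_row, class = ifelse(orientation == "antisense", "endo_siRNA",
                                   "gene_sense"), orientation)])
  cand <- merge(cand, aln[, .(aln_row, sequence)], by = "aln_row")
  cand[, prec := .precedence[class] * 2 + (orientation == "sense")]
  best <- cand[order(-prec)][!duplicated(sequence)]
  best[, label := ifelse(class %in% c("rRNA", "tRNA", "transposon"),
                         paste0(class, "_", orientation), class)]
  reads <- unique(aln[, .(sequence, count)], by = "sequence")
  out <- merge(reads, best[, .(sequence, label)], by = "sequence",
               all.x = TRUE, sort = FALSE)
  out[is.na(label), label := "unannotated"]
  out[]
}

#' Per-library class distribution
#'
#' @param read_labels output of [classify_reads()].
#' @return data.table with `label`, `reads` and `fraction`, zero-filled over
#'   the full label set (the input to a read-distribution summary figure).
#' @export
class_distribution <- function(read_labels) {
  d <- as.data.table(read_labels)[, .(reads = sum(count)), by = label]
  d <- merge(data.table(label = .class_labels), d, by = "label", all.x = TRUE)
  d[is.na(reads), reads := 0]
  d[, fraction := if (sum(reads) > 0) reads / sum(reads) else 0]
  d[match(.class_labels, label)]
}

#' Per-gene antisense (endo-siRNA) counts split by sub-region
#'
#' A read contributes to gene G iff a surviving alignment is antisense to
#' and fully contained in a 5'UTR, exon or 3'UTR of G. Multi-mappers
#' contribute `count / n_best` per alignment (fractional mode).
#'
#' @inheritParams classify_reads
#' @param count_mode `"fractional"` (default) or `"all"` (full count to
#'   every hit).
#' @return list with `by_subregion` (gene_id, subregion, count) and
#'   `by_gene` (gene_id, count), zero-filled over all annotated genes.
#' @export
count_endo_sirna <- function(alignments, annotation, window = 5L,
                             count_mode = "fractional") {
  genes <- annotation$features[class == "gene", id]
  no_sub <- setdiff(genes,
                    annotation$features[class %in%
                      c("five_prime_UTR", "exon", "three_prime_UTR"),
                      unique(parent)])
  if (length(no_sub))
    warning("genes without sub-features skipped: ",
            paste(no_sub, collapse = ", "))
  ann <- .annotate_alignments(alignments, annotation, window, count_mode)
  h <- merge(ann$hits[class == "gene" & orientation == "antisense"],
             ann$aln[, .(aln_row, weight)], by = "aln_row")
  by_sub <- h[, .(count = sum(weight)), by = .(gene_id, subregion)]
  by_gene <- h[, .(count = sum(weight)), by = gene_id]
  by_gene <- merge(data.table(gene_id = setdiff(genes, no_sub)), by_gene,
                   by = "gene_id", all.x = TRUE)
  by_gene[is.na(count), count := 0]
  setorder(by_gene, gene_id)
  list(by_subregion = by_sub[], by_gene = by_gene[])
}

# per-feature weighted counts for one library at a given level
.feature_counts <- function(alignments, annotation, level, window = 5L,
                            count_mode = "fractional") {
  ann <- .annotate_alignments(alignments, annotation, window, count_mode)
  aln <- ann$aln
  if (level == "mirna_arm") {
    ids <- annotation$mature[, paste0(mirna_id, ":", arm)]
    got <- aln[!is.na(mirna), .(count = sum(weight)), by = .(id = mirna)]
  } else if (level == "gene") {
    ids <- sort(annotation$features[class == "gene", id])
    h <- merge(ann$hits[class == "gene" & orientation == "antisense"],
               aln[, .(aln_row, weight)], by = "aln_row")
    got <- h[, .(count = sum(weight)), by = .(id = gene_id)]
  } else if (level == "pirna_locus") {
    ids <- sort(annotation$features[class == "piRNA_gene", id])
    h <- merge(ann$hits[class == "piRNA_gene" & orientation == "sense"],
               aln[, .(aln_row, weight)], by = "aln_row")
    got <- h[, .(count = sum(weight)), by = .(id = feature_id)]
  } else stop("unknown level: ", level, call. = FALSE)
  v <- setNames(numeric(length(ids)), ids)
  if (nrow(got)) v[got$id] <- got$count
  v
}

#' Count table container
#'
#' @param counts numeric matrix, features x libraries.
#' @param groups named character vector of group labels, one per column.
#' @return object of class `count_table` (the matrix with a `groups`
#'   attribute).
#' @export
count_table <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate library ids", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- colnames(counts)
  if (!setequal(names(groups), colnames(counts)))
    stop("group labels must cover all libraries", call. = FALSE)
  structure(counts, groups = groups[colnames(counts)], class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d features x %d libraries (groups: %s)\n",
              nrow(x), ncol(x),
              paste(unique(attr(x, "groups")), collapse = ", ")))
  print(head(unclass(x)))
  invisible(x)
}

#' Build a features x libraries count matrix
#'
#' @param aligned_libraries named list of per-library surviving alignments
#'   (each an `align_library()$alignments`).
#' @param annotation an [annotation_set()].
#' @param level `"mirna_arm"`, `"gene"` (antisense endo-siRNA counts) or
#'   `"pirna_locus"` (sense counts).
#' @param groups named character vector of group labels per library.
#' @param window,count_mode see [classify_reads()] / [count_endo_sirna()].
#' @return a [count_table()]; rows cover all annotated features at the
#'   level, zero-filled.
#' @export
build_count_matrix <- function(aligned_libraries, annotation,
                               level = c("mirna_arm", "gene", "pirna_locus"),
                               groups = NULL, window = 5L,
                               count_mode = "fractional") {
  level <- match.arg(level)
  stopifnot_named(aligned_libraries, "aligned_libraries")
  cols <- lapply(aligned_libraries, .feature_counts, annotation = annotation,
                 level = level, window = window, count_mode = count_mode)
  m <- do.call(cbind, cols)
  colnames(m) <- names(aligned_libraries)
  if (is.null(groups))
    groups <- setNames(sub("_[0-9]+$", "", colnames(m)), colnames(m))
  count_table(m, groups)
}

#' Partition a per-gene count table by Argonaute pathway
#'
#' @param table a per-gene [count_table()].
#' @param pathways data.frame `gene_id`, `pathway`
#'   (`annotation_set$pathways`). Duplicate membership is an error.
#' @return named list of [count_table()]s, one per pathway plus
#'   `unassigned`.
#' @export
partition_pathways <- function(table, pathways) {
  pathways <- as.data.table(pathways)
  dup <- unique(pathways$gene_id[duplicated(pathways$gene_id)])
  if (length(dup))
    stop("genes with duplicate pathway membership: ",
         paste(dup, collapse = ", "), call. = FALSE)
  groups <- attr(table, "groups")
  pws <- unique(c(intersect(.pathway_levels, pathways$pathway),
                  setdiff(pathways$pathway, .pathway_levels)))
  out <- list()
  for (p in pws) {
    g <- intersect(rownames(table), pathways[pathway == p, gene_id])
    out[[p]] <- count_table(unclass(table)[g, , drop = FALSE], groups)
  }
  rest <- setdiff(rownames(table), pathways$gene_id)
  out$unassigned <- count_table(unclass(table)[rest, , drop = FALSE], groups)
  out
}
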