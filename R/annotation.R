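# Typed container for genomic features, mature-miRNA 5' anchors and
# Argonaute-pathway gene membership.

#' Construct an annotation set
#'
#' @param features data.frame with columns `id`, `class`, `chrom`, `start0`
#'   (0-based), `end0` (exclusive), `strand` and `parent` (`NA` for top-level
#'   features; the host gene id for 5'UTR/exon/3'UTR sub-features).
#' @param mature data.frame of mature miRNA 5' anchors: `mirna_id`,
#'   `arm` (`"g"` guide / `"p"` passenger), `chrom`, `mature_5p_position0`,
#'   `strand`.
#' @param pathways data.frame mapping `gene_id` to `pathway`
#'   (CSR-1 / WAGO / ALG-3/4 / ERGO-1). A gene may appear at most once.
#' @param chrom_lengths optional named vector of chromosome lengths, used to
#'   check that features lie within bounds.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(features, mature = NULL, pathways = NULL,
                           chrom_lengths = NULL) {
  features <- as.data.table(features)
  need <- c("id", "class", "chrom", "start0", "end0", "strand", "parent")
  if (!all(need %in% names(features)))
    stop("features must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(features)) {
    if (any(features$end0 <= features$start0))
      stop("features must have positive width", call. = FALSE)
    if (!all(features$strand %in% c("+", "-")))
      stop("feature strand must be '+' or '-'", call. = FALSE)
    if (anyDuplicated(features$id))
      stop("feature ids must be unique", call. = FALSE)
    if (!is.null(chrom_lengths)) {
      lim <- chrom_lengths[features$chrom]
      if (any(is.na(lim)) || any(features$end0 > lim) ||
          any(features$start0 < 0L))
        stop("feature interval outside chromosome bounds", call. = FALSE)
    }
  }
  mature <- if (is.null(mature)) {
    data.table(mirna_id = character(), arm = character(), chrom = character(),
               mature_5p_position0 = integer(), strand = character())
  } else as.data.table(mature)
  if (nrow(mature)) {
    if (!all(mature$arm %in% c("g", "p")))
      stop("mature miRNA arm must be 'g' or 'p'", call. = FALSE)
    hp <- features[class == "miRNA"]
    m <- merge(mature, hp, by.x = c("mirna_id", "chrom"),
               by.y = c("id", "chrom"))
    if (nrow(m) < nrow(mature) ||
        any(m$mature_5p_position0 < m$start0 | m$mature_5p_position0 >= m$end0))
      stop("every mature miRNA 5' anchor must lie inside its hairpin locus",
           call. = FALSE)
  }
  pathways <- if (is.null(pathways)) {
    data.table(gene_id = character(), pathway = character())
  } else as.data.table(pathways)
  if (nrow(pathways)) {
    dup <- pathways$gene_id[duplicated(pathways$gene_id)]
    if (length(dup))
      stop("genes with duplicate pathway membership: ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    genes <- features[class == "gene", id]
    miss <- setdiff(pathways$gene_id, genes)
    if (length(miss))
      stop("pathway membership references unknown genes: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  structure(list(features = features, mature = mature, pathways = pathways),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "annotation_set: %d feature(s), %d mature miRNA arm(s), %d pathway gene(s)\n",
    nrow(x$features), nrow(x$mature), nrow(x$pathways)))
  if (nrow(x$features)) print(x$features[, .N, by = class])
  invisible(x)
}

#' Convert annotation features to GRanges
#'
#' @param annotation an [annotation_set()].
#' @param classes optional subset of feature classes to keep.
#' @return a [GenomicRanges::GRanges] with mcols `id`, `class`, `parent`.
#' @export
annotation_granges <- function(annotation, classes = NULL) {
  ft <- annotation$features
  if (!is.null(classes)) ft <- ft[class %in% classes]
  GenomicRanges::GRanges(
    seqnames = ft$chrom,
    ranges = IRanges::IRanges(start = ft$start0 + 1L, end = ft$end0),
    strand = ft$strand, id = ft$id, class = ft$class, parent = ft$parent)
}

# intergenic gaps (0-based half-open), at least `min_width` wide
.intergenic_windows <- function(genome, min_width = 40L) {
  ft <- genome$annotation$features[is.na(parent)]
  res <- rbindlist(lapply(names(genome$seqs), function(ch) {
    len <- nchar(genome$seqs[[ch]])
    f <- ft[chrom == ch][order(start0)]
    starts <- c(0L, f$end0); ends <- c(f$start0, len)
    keep <- ends - starts >= min_width
    data.table(chrom = ch, start0 = starts[keep], end0 = ends[keep])
  }))
  res
}
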