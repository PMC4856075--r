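# Synthetic annotated genome: a stand-in for a worm-style genome carrying
# miRNA hairpins (two mature arms each), piRNA loci (21U-style, sense 5' U),
# structural RNAs, transposons and protein-coding genes with
# 5'UTR/exon/3'UTR sub-features, plus Argonaute-pathway gene lists.

# fixed feature geometry (nt); chosen once as desk-scale caricatures of the
# real size ranges, see the methods vignette
.geom <- list(
  mirna_width      = 70L,  guide_5p_off = 2L,  pass_5p_off = 40L,
  pirna_width      = 30L,
  trna_width       = 70L,
  rrna_width       = 150L,
  transposon_width = 300L,
  utr5_width = 100L, exon_width = 200L, intron_width = 50L, utr3_width = 100L
)

.pathway_levels <- c("CSR-1", "WAGO", "ALG-3/4", "ERGO-1")

#' Specification of a synthetic genome
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of every chromosome in nt.
#' @param n_mirna,n_pirna,n_trna,n_rrna,n_transposon,n_gene feature counts.
#' @param seed integer seed; the same spec yields byte-identical output.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 2L, chrom_length = 30000L,
                        n_mirna = 30L, n_pirna = 30L, n_trna = 10L,
                        n_rrna = 5L, n_transposon = 10L, n_gene = 40L,
                        seed = 1L) {
  counts <- c(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
              n_mirna = n_mirna, n_pirna = n_pirna, n_trna = n_trna,
              n_rrna = n_rrna, n_transposon = n_transposon, n_gene = n_gene)
  for (nm in names(counts)) {
    if (!is_count(counts[[nm]]))
      stop(sprintf("'%s' must be a non-negative integer", nm), call. = FALSE)
  }
  if (n_chromosomes < 1L) stop("need at least one chromosome", call. = FALSE)
  structure(c(as.list(setNames(as.integer(counts), names(counts))),
              list(seed = as.integer(seed))),
            class = "genome_spec")
}

# one row per feature to be placed, in deterministic order
.feature_plan <- function(spec) {
  g <- .geom
  gene_width <- g$utr5_width + 2L * g$exon_width + g$intron_width + g$utr3_width
  mk <- function(class, n, width, prefix) {
    if (n == 0L) return(NULL)
    data.table(id = sprintf("%s%03d", prefix, seq_len(n)),
               class = class, width = width)
  }
  rbindlist(list(
    mk("miRNA", spec$n_mirna, g$mirna_width, "mir-"),
    mk("piRNA_gene", spec$n_pirna, g$pirna_width, "21ur-"),
    mk("tRNA", spec$n_trna, g$trna_width, "trn-"),
    mk("rRNA", spec$n_rrna, g$rrna_width, "rrn-"),
    mk("transposable_element", spec$n_transposon, g$transposon_width, "tn-"),
    mk("gene", spec$n_gene, gene_width, "gene-")
  ))
}

#' Build a synthetic annotated genome
#'
#' Places non-overlapping features sequentially with random intergenic gaps,
#' draws uniform random chromosome sequence, forces a 5' U (genomic T on the
#' sense strand) at every piRNA locus, anchors a guide and a passenger mature
#' 5' end inside every miRNA hairpin, equips every gene with
#' 5'UTR/exon/intron/exon/3'UTR sub-features, and assigns each gene to at
#' most one Argonaute small-RNA pathway.
#'
#' @param spec a [genome_spec()].
#' @return an object of class `srna_genome`: a list with elements `seqs`
#'   (named character vector of chromosome sequences), `annotation` (an
#'   [annotation_set()]) and `spec`.
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    plan <- .feature_plan(spec)
    chroms <- paste0("chr", as.character(utils::as.roman(seq_len(spec$n_chromosomes))))

    placed <- NULL
    if (!is.null(plan) && nrow(plan)) {
      plan[, strand := sample(c("+", "-"), .N, replace = TRUE)]
      plan[, gap := sample(20:80, .N, replace = TRUE)]
      # sequential packing across chromosomes
      chrom_i <- 1L; cursor <- 0L
      start0 <- integer(nrow(plan)); chrom <- character(nrow(plan))
      for (i in seq_len(nrow(plan))) {
        need <- plan$gap[i] + plan$width[i]
        while (cursor + need > spec$chrom_length) {
          chrom_i <- chrom_i + 1L
          cursor <- 0L
          if (chrom_i > spec$n_chromosomes)
            stop(sprintf("cannot place feature '%s': genome too small",
                         plan$id[i]), call. = FALSE)
        }
        start0[i] <- cursor + plan$gap[i]
        chrom[i] <- chroms[chrom_i]
        cursor <- start0[i] + plan$width[i]
      }
      placed <- copy(plan)[, `:=`(chrom = chrom, start0 = start0,
                                  end0 = start0 + width)]
    }

    seqs <- vapply(chroms, function(ch)
      paste(sample(c("A", "C", "G", "T"), spec$chrom_length, replace = TRUE),
            collapse = ""), character(1L))

    features <- data.table(id = character(), class = character(),
                           chrom = character(), start0 = integer(),
                           end0 = integer(), strand = character(),
                           parent = character())
    mature <- data.table(mirna_id = character(), arm = character(),
                         chrom = character(), mature_5p_position0 = integer(),
                         strand = character())
    pathways <- data.table(gene_id = character(), pathway = character())

    if (!is.null(placed) && nrow(placed)) {
      top <- placed[, .(id, class, chrom, start0, end0, strand,
                        parent = NA_character_)]
      g <- .geom
      gene_rows <- placed[class == "gene"]
      subs <- NULL
      if (nrow(gene_rows)) {
        subs <- rbindlist(lapply(seq_len(nrow(gene_rows)), function(i) {
          r <- gene_rows[i]
          # sub-feature layout in transcript order, reversed on minus strand
          w <- c(g$utr5_width, g$exon_width, g$intron_width, g$exon_width,
                 g$utr3_width)
          cls <- c("five_prime_UTR", "exon", "intron", "exon",
                   "three_prime_UTR")
          tag <- c("u5", "ex1", "in1", "ex2", "u3")
          if (r$strand == "-") { w <- rev(w); cls <- rev(cls); tag <- rev(tag) }
          off <- cumsum(c(0L, w[-length(w)]))
          keep <- cls != "intron"
          data.table(id = sprintf("%s:%s", r$id, tag[keep]),
                     class = cls[keep], chrom = r$chrom,
                     start0 = as.integer(r$start0 + off[keep]),
                     end0 = as.integer(r$start0 + off[keep] + w[keep]),
                     strand = r$strand, parent = r$id)
        }))
      }
      features <- if (is.null(subs)) top else rbind(top, subs)

      # force a genomic T at each piRNA sense 5' end (21U-RNA convention)
      pir <- placed[class == "piRNA_gene"]
      for (i in seq_len(nrow(pir))) {
        pos <- if (pir$strand[i] == "+") pir$start0[i] + 1L else pir$end0[i]
        base <- if (pir$strand[i] == "+") "T" else "A"
        substr(seqs[[pir$chrom[i]]], pos, pos) <- base
      }

      mir <- placed[class == "miRNA"]
      if (nrow(mir)) {
        anchor <- function(off5p) {
          # offset measured from the hairpin 5' end in transcript orientation
          ifelse(mir$strand == "+", mir$start0 + off5p,
                 mir$end0 - 1L - off5p)
        }
        mature <- rbind(
          data.table(mirna_id = mir$id, arm = "g", chrom = mir$chrom,
                     mature_5p_position0 = as.integer(anchor(g$guide_5p_off)),
                     strand = mir$strand),
          data.table(mirna_id = mir$id, arm = "p", chrom = mir$chrom,
                     mature_5p_position0 = as.integer(anchor(g$pass_5p_off)),
                     strand = mir$strand))
        setorder(mature, mirna_id, arm)
      }

      genes <- placed[class == "gene", id]
      if (length(genes)) {
        pw <- sample(c(.pathway_levels, NA_character_), length(genes),
                     replace = TRUE, prob = c(.25, .25, .15, .15, .20))
        pathways <- data.table(gene_id = genes, pathway = pw)[!is.na(pathway)]
      }
    }

    ann <- annotation_set(features, mature, pathways,
                          chrom_lengths = setNames(rep(spec$chrom_length,
                                                       length(chroms)), chroms))
    structure(list(seqs = seqs, annotation = ann, spec = spec),
              class = "srna_genome")
  })
}

#' @export
print.srna_genome <- function(x, ...) {
  cat(sprintf("srna_genome: %d chromosome(s) x %d nt, %d feature(s)\n",
              length(x$seqs), nchar(x$seqs[[1L]]),
              nrow(x$annotation$features)))
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

.sanitize_pathway <- function(p) gsub("[^A-Za-z0-9._-]", "_", p)

#' Write a synthetic genome and its annotation to disk
#'
#' Emits `genome.fa` (FASTA), `annotation.gff3` (1-based, inclusive GFF3),
#' `mature_mirna.tsv` and one `pathway_<name>.txt` gene list per pathway.
#' All outputs are byte-deterministic for a given genome object.
#'
#' @param genome an `srna_genome`.
#' @param dir output directory (created if missing).
#' @return invisibly, a named list of the paths written.
#' @export
write_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "srna_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seqs), fa)
  gff <- file.path(dir, "annotation.gff3")
  write_gff3(genome$annotation, gff)
  mat <- file.path(dir, "mature_mirna.tsv")
  write.table(genome$annotation$mature, mat, sep = "\t", quote = FALSE,
              row.names = FALSE)
  pw <- genome$annotation$pathways
  pw_paths <- character(0)
  for (p in unique(pw$pathway)) {
    f <- file.path(dir, sprintf("pathway_%s.txt", .sanitize_pathway(p)))
    writeLines(sort(pw[pathway == p, gene_id]), f)
    pw_paths <- c(pw_paths, setNames(f, p))
  }
  invisible(list(fasta = fa, gff3 = gff, mature = mat, pathways = pw_paths))
}

#' Write an annotation set as GFF3
#'
#' Coordinates are converted from the internal 0-based half-open convention
#' to GFF3's 1-based inclusive one. Sub-features carry a `Parent` attribute.
#'
#' @param annotation an [annotation_set()].
#' @param path output file.
#' @export
write_gff3 <- function(annotation, path) {
  ft <- copy(annotation$features)
  setorder(ft, chrom, start0, id)
  attrs <- ifelse(is.na(ft$parent), sprintf("ID=%s", ft$id),
                  sprintf("ID=%s;Parent=%s", ft$id, ft$parent))
  lines <- sprintf("%s\tsrnakit\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   ft$chrom, ft$class, ft$start0 + 1L, ft$end0, ft$strand,
                   attrs)
  writeLines(c("##gff-version 3", lines), path)
}

#' Read an annotation set back from disk
#'
#' @param gff3 path to a GFF3 file as written by [write_gff3()].
#' @param mature_tsv path to the mature-miRNA TSV (optional).
#' @param pathway_files named character vector of pathway list files, names
#'   giving the pathway labels (optional).
#' @return an [annotation_set()].
#' @export
read_annotation <- function(gff3, mature_tsv = NULL, pathway_files = NULL) {
  gr <- rtracklayer::import(gff3, format = "gff3")
  parent <- as.character(S4Vectors::mcols(gr)$Parent)
  parent[!nzchar(parent) | parent == "character(0)"] <- NA_character_
  features <- data.table(
    id = as.character(S4Vectors::mcols(gr)$ID),
    class = as.character(S4Vectors::mcols(gr)$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    parent = parent)
  mature <- if (is.null(mature_tsv)) {
    data.table(mirna_id = character(), arm = character(), chrom = character(),
               mature_5p_position0 = integer(), strand = character())
  } else {
    setDT(read.table(mature_tsv, sep = "\t", header = TRUE,
                     colClasses = c("character", "character", "character",
                                    "integer", "character")))
  }
  pathways <- data.table(gene_id = character(), pathway = character())
  if (!is.null(pathway_files)) {
    stopifnot_named(pathway_files, "pathway_files")
    pathways <- rbindlist(lapply(names(pathway_files), function(p)
      data.table(gene_id = readLines(pathway_files[[p]]), pathway = p)))
  }
  annotation_set(features, mature, pathways)
}
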