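ann <- toy_annotation()

test_that("miRNA assignment follows the -5..+5 window on the sense strand", {
  # guide anchor at 102 on +
  expect_equal(assign_mirna(toy_aln(102), ann$mature), "mirX:g")
  expect_equal(assign_mirna(toy_aln(97), ann$mature), "mirX:g")    # -5
  expect_equal(assign_mirna(toy_aln(107), ann$mature), "mirX:g")   # +5
  expect_true(is.na(assign_mirna(toy_aln(108), ann$mature)))       # +6
  expect_true(is.na(assign_mirna(toy_aln(96), ann$mature)))        # -6
  # antisense read whose 5' end (end0 - 1) is inside the window: rejected
  anti <- toy_aln(102 - 21)  # end0 - 1 == 102
  anti$strand <- "-"
  expect_true(is.na(assign_mirna(anti, ann$mature)))
  # tie between overlapping anchors resolves to the nearest
  expect_equal(assign_mirna(toy_aln(137), ann$mature), "mirX:p")
  # equidistant tie: guide beats passenger
  m2 <- data.table::data.table(
    mirna_id = c("m", "m"), arm = c("p", "g"), chrom = "chrT",
    mature_5p_position0 = c(98L, 106L), strand = "+")
  expect_equal(assign_mirna(toy_aln(102), m2), "m:g")
})

test_that("window sharpness: exactly offsets -5..+5 are assigned", {
  offsets <- -8:8
  got <- assign_mirna(data.table::rbindlist(
    lapply(102 + offsets, toy_aln)), ann$mature)
  expect_equal(!is.na(got), abs(offsets) <= 5)
})

test_that("feature assignment requires full containment", {
  # fully inside the + strand tRNA (400-470), antisense read
  h <- assign_features(toy_aln(410, strand = "-"), ann)
  expect_equal(h$feature_id, "trnX")
  expect_equal(h$orientation, "antisense")
  # straddling the tRNA start: not reported
  h2 <- assign_features(toy_aln(395), ann)
  expect_equal(nrow(h2), 0L)
  # inside an exon: both the exon (as gene) containment is reported once
  h3 <- assign_features(toy_aln(700), ann)
  expect_equal(h3$feature_id, "geneX")
  expect_equal(h3$subregion, "exon")
})

test_that("nested features are each reported", {
  ft <- rbind(ann$features,
              data.table::data.table(id = "trnY", class = "tRNA",
                                     chrom = "chrT", start0 = 405L,
                                     end0 = 460L, strand = "+",
                                     parent = NA_character_))
  ann2 <- annotation_set(ft, ann$mature, ann$pathways)
  h <- assign_features(toy_aln(410, len = 22L), ann2)
  expect_setequal(h$feature_id, c("trnX", "trnY"))
})

test_that("endo-siRNA counting is antisense-only with sub-region split", {
  a <- rbind(toy_aln(700, strand = "-", count = 3L),   # antisense exon
             toy_aln(610, len = 20L, strand = "-"),    # antisense 5'UTR
             toy_aln(730, strand = "+", count = 5L))   # sense exon: excluded
  res <- count_endo_sirna(a, ann)
  expect_equal(res$by_gene[gene_id == "geneX", count], 4)
  expect_equal(res$by_subregion[subregion == "exon", count], 3)
  expect_equal(res$by_subregion[subregion == "five_prime_UTR", count], 1)
})

test_that("genes without sub-features are skipped with a warning", {
  ft <- rbind(ann$features,
              data.table::data.table(id = "geneY", class = "gene",
                                     chrom = "chrT", start0 = 950L,
                                     end0 = 1100L, strand = "+",
                                     parent = NA_character_))
  ann2 <- annotation_set(ft, ann$mature, ann$pathways)
  expect_warning(res <- count_endo_sirna(toy_aln(700, strand = "-"), ann2),
                 "geneY")
  expect_false("geneY" %in% res$by_gene$gene_id)
})

test_that("multi-mappers contribute fractional weight count/n", {
  a <- toy_aln(700, strand = "-", count = 6L, n_best = 3L)
  res <- count_endo_sirna(a, ann)
  expect_equal(res$by_gene[gene_id == "geneX", count], 2)
  res_all <- count_endo_sirna(a, ann, count_mode = "all")
  expect_equal(res_all$by_gene[gene_id == "geneX", count], 6)
})

test_that("single-label classification follows the precedence", {
  # miRNA beats containment in other features
  lab <- classify_reads(toy_aln(102, sequence = "R1"), ann)
  expect_equal(lab$label, "miRNA")
  # antisense exon only: endo-siRNA
  lab2 <- classify_reads(toy_aln(700, strand = "-", sequence = "R2"), ann)
  expect_equal(lab2$label, "endo_siRNA")
  # sense exon: gene_sense
  lab3 <- classify_reads(toy_aln(700, sequence = "R3"), ann)
  expect_equal(lab3$label, "gene_sense")
  # piRNA locus sense
  lab4 <- classify_reads(toy_aln(305, len = 21L, sequence = "R4"), ann)
  expect_equal(lab4$label, "piRNA")
  # piRNA locus antisense falls through to unannotated
  lab5 <- classify_reads(toy_aln(305, len = 21L, strand = "-",
                                 sequence = "R5"), ann)
  expect_equal(lab5$label, "unannotated")
  # unannotated region
  lab6 <- classify_reads(toy_aln(30, sequence = "R6"), ann)
  expect_equal(lab6$label, "unannotated")
  # distribution partitions all reads exactly once
  all <- data.table::rbindlist(list(
    toy_aln(102, sequence = "R1", count = 4L),
    toy_aln(700, strand = "-", sequence = "R2", count = 2L),
    toy_aln(30, sequence = "R6")))
  dist <- class_distribution(classify_reads(all, ann))
  expect_equal(sum(dist$reads), 7)
  expect_equal(sum(dist$fraction), 1)
})

test_that("count matrices are zero-filled with deterministic shape", {
  g <- build_genome(genome_spec(n_mirna = 10, n_gene = 6, n_pirna = 4,
                                n_trna = 2, n_rrna = 1, n_transposon = 2,
                                chrom_length = 12000, seed = 130))
  ex <- simulate_libraries(g, library_spec(reads_per_library = 500,
                                           error_rate = 0, seed = 131))
  pp <- preprocess_reads(data.table::rbindlist(ex$reads), ex$barcode_map,
                         trim_spec())
  idx <- genome_index(g)
  alns <- lapply(pp$collapsed, function(cc) align_library(cc, idx)$alignments)
  ct <- build_count_matrix(alns, g$annotation, "mirna_arm")
  expect_equal(dim(ct), c(20L, 6L))
  expect_equal(unname(attr(ct, "groups")),
               rep(c("wt", "mut"), each = 3))
  # zero rows are retained
  ct0 <- build_count_matrix(alns["wt_1"], g$annotation, "pirna_locus")
  expect_equal(nrow(ct0), 4L)
  # per-library miRNA column total equals the per-read miRNA label total
  lab <- classify_reads(alns$wt_1, g$annotation)
  expect_equal(sum(ct[, "wt_1"]),
               lab[label == "miRNA", sum(count)])
  expect_error(build_count_matrix(setNames(alns[c(1, 1)], c("a", "a")),
                                  g$annotation, "gene"),
               "unique non-empty names")
})

test_that("pathway partitioning conserves and isolates genes", {
  m <- matrix(c(7, 3, 2, 5, 0, 1), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("l1", "l2")))
  ct <- count_table(m, c(l1 = "wt", l2 = "mut"))
  pw <- data.table::data.table(gene_id = c("g1", "g2"),
                               pathway = c("WAGO", "CSR-1"))
  parts <- partition_pathways(ct, pw)
  expect_equal(rownames(parts$WAGO), "g1")
  expect_equal(unname(unclass(parts$WAGO)["g1", ]), c(7, 5))
  expect_equal(rownames(parts$unassigned), "g3")
  # conservation across the partition
  tot <- Reduce(`+`, lapply(parts, function(p) sum(unclass(p))))
  expect_equal(tot, sum(m))
  # empty pathway: absent table but others unchanged
  expect_false("ALG-3/4" %in% names(parts))
  expect_error(partition_pathways(ct, rbind(pw,
    data.table::data.table(gene_id = "g1", pathway = "CSR-1"))),
    "duplicate pathway membership")
})

test_that("synthetic truth: per-pathway tables partition the gene set", {
  g <- build_genome(genome_spec(seed = 140))
  pw <- g$annotation$pathways
  m <- matrix(1, nrow = g$spec$n_gene, ncol = 2,
              dimnames = list(sort(g$annotation$features[class == "gene",
                                                         id]),
                              c("a", "b")))
  parts <- partition_pathways(count_table(m, c(a = "wt", b = "mut")), pw)
  expect_equal(sum(vapply(parts, nrow, 0L)), g$spec$n_gene)
  for (p in setdiff(names(parts), "unassigned"))
    expect_equal(sort(rownames(parts[[p]])), sort(pw[pathway == p, gene_id]))
})
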