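test_that("build_genome places the requested features with full structure", {
  g <- build_genome(genome_spec(n_mirna = 5, n_gene = 8, seed = 3))
  ft <- g$annotation$features
  expect_equal(nrow(ft[class == "miRNA"]), 5L)
  expect_equal(nrow(g$annotation$mature), 10L)  # guide + passenger per locus
  expect_setequal(g$annotation$mature$arm, c("g", "p"))
  # every gene has all three sub-region types
  subs <- ft[!is.na(parent), .(types = list(sort(unique(class)))), by = parent]
  expect_equal(nrow(subs), 8L)
  for (tt in subs$types)
    expect_equal(tt, c("exon", "five_prime_UTR", "three_prime_UTR"))
  # non-overlapping top-level features
  top <- ft[is.na(parent)][order(chrom, start0)]
  gap <- top[, .(ok = all(start0[-1] >= head(end0, -1))), by = chrom]
  expect_true(all(gap$ok))
  # at most one pathway per gene
  expect_equal(anyDuplicated(g$annotation$pathways$gene_id), 0L)
  # mature anchors inside hairpins on the hairpin strand
  m <- merge(g$annotation$mature, ft[class == "miRNA"],
             by.x = "mirna_id", by.y = "id")
  expect_true(all(m$mature_5p_position0 >= m$start0 &
                    m$mature_5p_position0 < m$end0))
  expect_true(all(m$strand.x == m$strand.y))
})

test_that("piRNA loci start with genomic T on the sense strand", {
  g <- build_genome(genome_spec(seed = 5))
  pir <- g$annotation$features[class == "piRNA_gene"]
  first <- ifelse(pir$strand == "+",
                  substring(g$seqs[pir$chrom], pir$start0 + 1, pir$start0 + 1),
                  substring(g$seqs[pir$chrom], pir$end0, pir$end0))
  expect_true(all(ifelse(pir$strand == "+", first == "T", first == "A")))
})

test_that("infeasible specs fail naming the first unplaceable feature", {
  expect_error(build_genome(genome_spec(n_chromosomes = 1,
                                        chrom_length = 500, n_mirna = 10)),
               "cannot place feature")
})

test_that("same seed gives byte-identical genome and library output", {
  out <- replicate(2, {
    g <- build_genome(genome_spec(n_mirna = 4, n_gene = 4, n_pirna = 4,
                                  n_trna = 2, n_rrna = 1, n_transposon = 2,
                                  chrom_length = 8000, seed = 11))
    ex <- simulate_libraries(g, library_spec(reads_per_library = 400,
                                             seed = 12))
    d <- tempfile(); dir.create(d)
    write_genome(g, d)
    write_fastq(ex$reads$wt_1, file.path(d, "wt_1.fastq.gz"))
    d
  })
  for (f in c("genome.fa", "annotation.gff3", "mature_mirna.tsv",
              "wt_1.fastq.gz")) {
    expect_identical(readBin(file.path(out[[1]], f), "raw", 10^7),
                     readBin(file.path(out[[2]], f), "raw", 10^7),
                     label = f)
  }
  # and a different seed changes the reads
  g <- build_genome(genome_spec(n_mirna = 4, n_gene = 4, n_pirna = 4,
                                n_trna = 2, n_rrna = 1, n_transposon = 2,
                                chrom_length = 8000, seed = 11))
  ex2 <- simulate_libraries(g, library_spec(reads_per_library = 400,
                                            seed = 13))
  ex1 <- simulate_libraries(g, library_spec(reads_per_library = 400,
                                            seed = 12))
  expect_false(identical(ex1$reads$wt_1$sequence, ex2$reads$wt_1$sequence))
})

test_that("GFF3 round-trip reproduces the annotation set", {
  g <- build_genome(genome_spec(n_mirna = 3, n_gene = 3, chrom_length = 9000,
                                seed = 21))
  d <- tempfile(); dir.create(d)
  paths <- write_genome(g, d)
  back <- read_annotation(paths$gff3, paths$mature, paths$pathways)
  orig <- g$annotation
  setkey(orig$features, id); setkey(back$features, id)
  expect_equal(back$features, orig$features)
  expect_equal(back$mature[order(mirna_id, arm)],
               orig$mature[order(mirna_id, arm)])
  expect_equal(back$pathways[order(gene_id)], orig$pathways[order(gene_id)])
})

test_that("ground truth conserves reads and respects class structure", {
  g <- build_genome(genome_spec(seed = 7))
  ex <- simulate_libraries(g, library_spec(reads_per_library = 2000,
                                           error_rate = 0, seed = 8))
  expect_equal(ex$truth[, .N, by = library]$N, rep(2000L, 6L))
  expect_equal(length(ex$reads), 6L)
  expect_equal(anyDuplicated(ex$truth$read_id), 0L)
  # piRNA reads are 21 nt sense-strand 5' U
  pir <- ex$truth[class == "pirna"]
  expect_true(all(nchar(pir$insert) == 21L))
  expect_true(all(substr(pir$insert, 1, 1) == "T"))
  # miRNA offsets stay in the configured -2..+2 window
  expect_true(all(abs(ex$truth[class == "mirna", offset5p]) <= 2L))
  # endo-siRNA reads are antisense to their gene
  gs <- g$annotation$features[class == "gene", .(feature_id = id,
                                                 gstrand = strand)]
  es <- merge(ex$truth[class == "endo_sirna"], gs, by = "feature_id")
  expect_true(all(es$strand != es$gstrand))
  # error-free reads are barcode + insert + adapter prefix
  r1 <- merge(ex$reads$mut_2, ex$truth[library == "mut_2"],
              by.x = "id", by.y = "read_id")
  expect_true(all(startsWith(r1$sequence,
                             paste0(ex$barcode_map[["mut_2"]], r1$insert))))
})

test_that("empty libraries are valid and warned about", {
  g <- build_genome(genome_spec(n_mirna = 2, n_gene = 2, n_pirna = 1,
                                n_trna = 1, n_rrna = 1, n_transposon = 1,
                                chrom_length = 6000, seed = 2))
  expect_warning(ex <- simulate_libraries(
    g, library_spec(reads_per_library = 0, seed = 1)), "empty")
  expect_equal(nrow(ex$truth), 0L)
  f <- tempfile(fileext = ".fastq")
  write_fastq(ex$reads$wt_1, f)
  expect_equal(nrow(read_fastq(f)), 0L)
})

test_that("empirical class proportions converge to the configured ones", {
  g <- build_genome(genome_spec(seed = 30))
  ex <- simulate_libraries(g, library_spec(reads_per_library = 100000,
                                           n_libraries_per_group = 1,
                                           error_rate = 0, seed = 31))
  props <- ex$truth[library == "wt_1", .N / 1e5, by = class]
  want <- library_spec(seed = 1)$class_proportions
  expect_true(all(abs(props$V1 - want[props$class]) <= 0.01))
})

test_that("spiked features shift mutant counts by the requested fold", {
  # one gene spiked 4-fold; mutant/wild-type mean ratio across seeds 1-10
  # sits within 3 standard errors of 4 (multinomial renormalization makes
  # the model expectation itself fractionally below 4)
  ratios <- vapply(1:10, function(s) {
    g <- build_genome(genome_spec(seed = 100))
    ex <- simulate_libraries(g, library_spec(
      reads_per_library = 20000, error_rate = 0,
      spike_table = data.frame(feature_id = "gene-010", fold_change = 4),
      seed = s))
    cnt <- ex$truth[feature_id == "gene-010", .N, by = library]
    cnt <- merge(data.table(library = names(ex$groups),
                            group = ex$groups), cnt, by = "library")
    cnt[is.na(N), N := 0L]
    cnt[group == "mut", mean(N)] / cnt[group == "wt", mean(N)]
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 4), 3 * se + 1e-12)
})

test_that("structural fidelity: at zero error rate trimming recovers every insert", {
  g <- build_genome(genome_spec(seed = 40))
  ex <- simulate_libraries(g, library_spec(reads_per_library = 3000,
                                           error_rate = 0, seed = 41))
  for (lib in c("wt_1", "mut_3")) {
    tr <- trim_reads(ex$reads[[lib]]$sequence, trim_spec())
    expect_true(all(tr$status == "trimmed"))
    bc <- ex$barcode_map[[lib]]
    recovered <- substring(tr$sequence, nchar(bc) + 1L)
    expect_identical(recovered, ex$truth[library == lib, insert])
  }
})

test_that("barcodes are unique, equal length, pairwise Hamming >= 2", {
  bc <- make_barcodes(8)
  expect_equal(length(unique(bc)), 8L)
  expect_equal(unique(nchar(bc)), 4L)
  for (i in 1:7) for (j in (i + 1):8) {
    d <- sum(strsplit(bc[i], "")[[1]] != strsplit(bc[j], "")[[1]])
    expect_gte(d, 2L)
  }
})
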