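# Independent oracles and tiny fixtures used across the suite.

library(data.table)

# exhaustive Hamming scan over every offset and both strands; the reference
# for the best-stratum alignment contract
oracle_align <- function(seq, seqs, max_mm = 3L) {
  hits <- list()
  for (ch in names(seqs)) {
    g <- strsplit(seqs[[ch]], "")[[1L]]
    n <- length(g)
    for (strand in c("+", "-")) {
      r <- strsplit(if (strand == "+") seq else srnakit::revcomp(seq),
                    "")[[1L]]
      L <- length(r)
      if (n < L) next
      noff <- n - L + 1L
      mm <- integer(noff)
      for (i in seq_len(L)) mm <- mm + (g[i:(i + noff - 1L)] != r[i])
      ok <- which(mm <= max_mm)
      if (length(ok))
        hits[[length(hits) + 1L]] <-
          data.table(chrom = ch, start0 = ok - 1L, strand = strand,
                     mm = mm[ok])
    }
  }
  if (!length(hits)) {
    return(data.table(chrom = character(), start0 = integer(),
                      strand = character(), mm = integer()))
  }
  out <- rbindlist(hits)
  out <- out[mm == min(mm)]
  setorder(out, chrom, start0, strand)
  out[]
}

# conditional NB split distribution via the gamma-function route: the
# per-library mean cancels, leaving only the size parameters
oracle_exact_p <- function(s1, s2, n1, n2, dispersion) {
  s <- s1 + s2
  if (s == 0) return(1)
  r1 <- n1 / dispersion; r2 <- n2 / dispersion
  k <- 0:s
  lw <- lgamma(k + r1) - lgamma(k + 1) + lgamma(s - k + r2) - lgamma(s - k + 1)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  min(1, 2 * min(sum(w[k <= s1]), sum(w[k >= s1])))
}

# doubled-tail conditional binomial (Poisson limit of the exact test)
oracle_binom_p <- function(s1, s, p1) {
  lower <- pbinom(s1, s, p1)
  upper <- 1 - pbinom(s1 - 1, s, p1)
  min(1, 2 * min(lower, upper))
}

# two-sided t-tail by numerical integration of the density
oracle_t_p <- function(stat, df) {
  2 * stats::integrate(function(x) stats::dt(x, df), abs(stat), Inf,
                       rel.tol = 1e-12)$value
}

# random DNA string helper
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# hand-built annotation: one chromosome, one miRNA hairpin with two arms,
# one piRNA locus, one tRNA, one gene with 5'UTR/exon/3'UTR
toy_annotation <- function() {
  features <- data.table(
    id = c("mirX", "pirX", "trnX", "geneX", "geneX:u5", "geneX:ex1",
           "geneX:u3"),
    class = c("miRNA", "piRNA_gene", "tRNA", "gene", "five_prime_UTR",
              "exon", "three_prime_UTR"),
    chrom = "chrT",
    start0 = c(100L, 300L, 400L, 600L, 600L, 650L, 850L),
    end0 = c(170L, 330L, 470L, 900L, 650L, 850L, 900L),
    strand = c("+", "+", "+", "+", "+", "+", "+"),
    parent = c(NA, NA, NA, NA, "geneX", "geneX", "geneX"))
  mature <- data.table(
    mirna_id = c("mirX", "mirX"), arm = c("g", "p"), chrom = "chrT",
    mature_5p_position0 = c(102L, 140L), strand = "+")
  srnakit::annotation_set(features, mature,
                          data.table(gene_id = "geneX", pathway = "WAGO"))
}

# an alignment row for toy_annotation tests
toy_aln <- function(start0, len = 22L, strand = "+", chrom = "chrT",
                    mm = 0L, count = 1L, n_best = 1L,
                    sequence = strrep("A", len)) {
  data.table(sequence = sequence, chrom = chrom, start0 = as.integer(start0),
             end0 = as.integer(start0 + len), strand = strand, mm = mm,
             count = count, n_best = n_best)
}
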