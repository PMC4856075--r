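# Statistics used for scoring genetic-interaction phenotypes: a Pearson
# chi-square test on penetrance contingency tables (adult alae categories,
# ASE neuron marker) and a two-tailed two-sample t test on per-animal seam
# cell counts (Welch by default).

#' Significance stars
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `N.S.` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star codes.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "N.S."), right = FALSE) |> as.character()
}

#' Chi-square test on a penetrance table
#'
#' Pearson statistic without continuity correction on raw animal counts;
#' rows are genotypes, columns phenotype categories (for example complete /
#' gapped / absent adult alae).
#'
#' @param table numeric matrix of non-negative integer counts, at least 2x2.
#' @return list with `statistic`, `df`, `pvalue`, `expected`,
#'   `low_expected` (TRUE if any expected cell < 5) and `stars`.
#' @export
chisq_penetrance <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("penetrance table must be at least 2x2", call. = FALSE)
  if (any(m < 0) || any(m != floor(m)))
    stop("penetrance tables must contain raw non-negative integer counts",
         call. = FALSE)
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0)) stop("row with zero total", call. = FALSE)
  if (any(cs == 0))
    stop("degenerate table: column with zero total", call. = FALSE)
  expected <- outer(rs, cs) / n
  stat <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  p <- pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, pvalue = p, expected = expected,
       low_expected = any(expected < 5), stars = significance_stars(p))
}

#' Two-tailed two-sample t test on seam cell counts
#'
#' Welch's unequal-variance t with Welch-Satterthwaite degrees of freedom by
#' default; `pooled = TRUE` gives the classical equal-variance test.
#'
#' @param a,b numeric vectors of per-animal counts, each of length >= 2.
#' @param pooled use the pooled-variance test (default FALSE).
#' @return list with `statistic`, `df`, `pvalue`, `method` and `stars`.
#' @export
seam_cell_t_test <- function(a, b, pooled = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 animals per genotype", call. = FALSE)
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  dm <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (dm == 0)
      return(list(statistic = 0, df = na + nb - 2L, pvalue = 1,
                  method = if (pooled) "pooled" else "welch",
                  stars = "N.S.", infinite = FALSE))
    return(list(statistic = sign(dm) * Inf, df = na + nb - 2L, pvalue = 0,
                method = if (pooled) "pooled" else "welch", stars = "***",
                infinite = TRUE))
  }
  if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  stat <- dm / se
  p <- 2 * pt(-abs(stat), df)
  list(statistic = stat, df = df, pvalue = p,
       method = if (pooled) "pooled" else "welch",
       stars = significance_stars(p), infinite = FALSE)
}

#' Read a penetrance table from TSV
#'
#' First column = genotype labels (row names), remaining columns =
#' phenotype-category counts.
#'
#' @param path TSV file.
#' @return integer matrix with genotype row names.
#' @export
read_penetrance_tsv <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  m
}
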