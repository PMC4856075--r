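# Count-based differential expression for a two-group small RNA experiment:
# TMM normalization, quantile-adjusted conditional maximum likelihood (qCML)
# common dispersion, the conditional negative binomial exact test with
# doubled-tail two-sided p-values, and Benjamini-Hochberg FDR control.

.as_counts <- function(table) {
  m <- unclass(as.matrix(table))
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("lib", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
  m
}

.get_groups <- function(table, groups) {
  if (is.null(groups)) groups <- attr(table, "groups")
  if (is.null(groups)) stop("group labels required", call. = FALSE)
  lev <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
  g <- as.character(groups)
  if (!is.null(names(groups))) g <- g[match(colnames(table), names(groups))]
  factor(g, levels = lev)
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: the reference library is the one whose
#' upper-quartile count fraction is closest to the mean; each library's
#' factor is 2 to the inverse-variance-weighted mean of M-values after
#' trimming the extreme `trim_M` of M and `trim_A` of A; factors are
#' rescaled to geometric mean 1.
#'
#' @param table count matrix or [count_table()] (features x libraries).
#' @param trim_M two-sided trim fraction on log-ratios (default 0.30).
#' @param trim_A two-sided trim fraction on average log-abundance
#'   (default 0.05).
#' @return named numeric vector of scaling factors, geometric mean 1.
#' @export
tmm_factors <- function(table, trim_M = 0.30, trim_A = 0.05) {
  counts <- .as_counts(table)
  if (ncol(counts) < 2L) stop("need at least 2 libraries", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("library with zero total: ",
         paste(colnames(counts)[lib == 0], collapse = ", "), call. = FALSE)
  f75 <- apply(counts, 2L, quantile, probs = 0.75, names = FALSE) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j)
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_M, trim_A),
    numeric(1L))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

.tmm_pair <- function(obs, ref, nO, nR, trim_M, trim_A) {
  keep0 <- obs > 0 & ref > 0
  obs <- obs[keep0]; ref <- ref[keep0]
  if (!length(obs)) return(1)
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * trim_M) + 1; hiL <- n + 1 - loL
  loS <- floor(n * trim_A) + 1; hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  fw <- sum(logR[keep] / v[keep], na.rm = TRUE) /
    sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(fw)) fw <- 0
  2^fw
}

# moderated quantile matching of a NB(input.mean, dispersion) count onto a
# NB(output.mean, dispersion) scale: average of the normal- and
# gamma-approximation quantile transforms
q2qnbinom <- function(x, input.mean, output.mean, dispersion = 0) {
  eps <- 1e-10
  input.mean <- pmax(input.mean, eps); output.mean <- pmax(output.mean, eps)
  ri <- 1 + dispersion * input.mean
  ro <- 1 + dispersion * output.mean
  vi <- input.mean * ri; vo <- output.mean * ro
  q_norm <- output.mean + sqrt(vo / vi) * (x - input.mean)
  p <- pgamma(x, shape = input.mean / ri, scale = ri)
  q_gam <- qgamma(p, shape = output.mean / ro, scale = ro)
  pmax((q_norm + q_gam) / 2, 0)
}

# pseudo-counts at the common (geometric mean) effective library size,
# computed per group under a common within-group rate
.equalize <- function(counts, groups, dispersion, eff) {
  common <- exp(mean(log(eff)))
  pseudo <- counts
  for (g in levels(groups)) {
    j <- which(groups == g)
    rate <- rowSums(counts[, j, drop = FALSE]) / sum(eff[j])
    for (jj in j) {
      pseudo[, jj] <- q2qnbinom(counts[, jj], rate * eff[jj], rate * common,
                                dispersion)
    }
  }
  list(pseudo = pseudo, common = common)
}

# summed conditional log-likelihood of a common dispersion given per-group
# pseudo-count totals (terms free of the dispersion dropped)
.cond_ll <- function(dispersion, pseudo, groups) {
  r <- 1 / dispersion
  tot <- 0
  for (g in levels(groups)) {
    y <- pseudo[, groups == g, drop = FALSE]
    n <- ncol(y)
    if (n < 2L) next
    z <- rowSums(y)
    tot <- tot + sum(rowSums(lgamma(y + r)) + lgamma(n * r) -
                       lgamma(z + n * r) - n * lgamma(r))
  }
  tot
}

#' qCML common dispersion estimate
#'
#' Counts are converted to pseudo-counts at equalized effective library
#' sizes by moderated quantile matching, and a single dispersion shared by
#' all features maximizes the summed conditional log-likelihood given the
#' per-group pseudo totals. The search is on the log scale over
#' `[1e-6, 10]`; equalization and maximization alternate to convergence.
#'
#' @param table count matrix or [count_table()].
#' @param groups group labels per library (defaults to the table's groups).
#' @param norm normalization factors from [tmm_factors()] (computed if
#'   `NULL`).
#' @return the dispersion estimate (a single non-negative number).
#' @export
estimate_common_dispersion <- function(table, groups = NULL, norm = NULL) {
  counts <- .as_counts(table)
  groups <- .get_groups(counts, if (is.null(groups)) attr(table, "groups")
                                else groups)
  if (!any(table(groups) >= 2L))
    stop("no group has replication; supply a dispersion explicitly",
         call. = FALSE)
  if (is.null(norm)) norm <- tmm_factors(table)
  eff <- colSums(counts) * norm
  disp <- 0.01
  for (iter in 1:5) {
    eq <- .equalize(counts, groups, disp, eff)
    opt <- optimize(function(ld) .cond_ll(exp(ld), eq$pseudo, groups),
                    c(log(1e-6), log(10)), maximum = TRUE, tol = 1e-6)
    new <- exp(opt$maximum)
    if (abs(new - disp) < 1e-6) { disp <- new; break }
    disp <- new
  }
  disp
}

# two-sided doubled-tail conditional NB exact p-value for one feature
.exact_nb_p <- function(s1, s2, n1, n2, dispersion) {
  s <- s1 + s2
  if (s == 0) return(1)
  if (dispersion < 1e-10) {
    p1 <- n1 / (n1 + n2)
    lower <- pbinom(s1, s, p1)
    upper <- 1 - pbinom(s1 - 1L, s, p1)
    return(min(1, 2 * min(lower, upper)))
  }
  mu <- s / (n1 + n2)
  k <- 0:s
  lp <- dnbinom(k, size = n1 / dispersion, mu = n1 * mu, log = TRUE) +
    dnbinom(s - k, size = n2 / dispersion, mu = n2 * mu, log = TRUE)
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  min(1, 2 * min(sum(pr[k <= s1]), sum(pr[k >= s1])))
}

#' Negative binomial exact test
#'
#' For each feature, the two-sided p-value is the doubled smaller
#' conditional tail (capped at 1) of the split of the feature's pseudo-count
#' total between the two groups, under a negative binomial model at the
#' supplied common dispersion and equalized library sizes. Log fold changes
#' use normalized group mean rates with a proportional prior count.
#'
#' @param table count matrix or [count_table()].
#' @param groups two group labels per library; the first factor level is the
#'   reference (denominator of the fold change).
#' @param norm factors from [tmm_factors()] (computed if `NULL`).
#' @param dispersion common NB dispersion (e.g. from
#'   [estimate_common_dispersion()]).
#' @param prior_count proportional prior count per library used only for
#'   `logFC`/`logCPM` stabilization (default 0.125).
#' @return data.table: `feature`, `logFC` (log2 second group / first group),
#'   `logCPM`, `pvalue`, `all_zero`.
#' @export
exact_test_nb <- function(table, groups = NULL, norm = NULL, dispersion,
                          prior_count = 0.125) {
  counts <- .as_counts(table)
  groups <- .get_groups(counts, if (is.null(groups)) attr(table, "groups")
                                else groups)
  if (nlevels(groups) != 2L)
    stop("exact test requires exactly 2 groups", call. = FALSE)
  if (is.null(norm)) norm <- tmm_factors(table)
  eff <- colSums(counts) * norm
  eq <- .equalize(counts, groups, dispersion, eff)
  g1 <- which(groups == levels(groups)[1L])
  g2 <- which(groups == levels(groups)[2L])
  s1 <- round(rowSums(eq$pseudo[, g1, drop = FALSE]))
  s2 <- round(rowSums(eq$pseudo[, g2, drop = FALSE]))
  pv <- vapply(seq_along(s1), function(i)
    .exact_nb_p(s1[i], s2[i], length(g1), length(g2), dispersion),
    numeric(1L))
  prior <- prior_count * eff / mean(eff)
  rate <- function(j) rowSums(sweep(counts[, j, drop = FALSE], 2L, prior[j],
                                    `+`)) / sum(eff[j] + 2 * prior[j])
  logFC <- log2(rate(g2) / rate(g1))
  logCPM <- log2((rowSums(counts) + 2 * prior_count * ncol(counts)) /
                   sum(eff) * 1e6)
  zero <- rowSums(counts) == 0
  logFC[zero] <- 0; pv[zero] <- 1
  data.table(feature = rownames(counts), logFC = logFC, logCPM = logCPM,
             pvalue = pv, all_zero = zero)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure: monotone non-decreasing in p-value rank, capped at 1.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted values (FDR) in the original order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues) | pvalues < 0 | pvalues > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  n <- length(pvalues)
  if (n == 0L) return(numeric(0))
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * pvalues[o]))[ro]
}

#' Two-group differential expression pipeline
#'
#' TMM factors, qCML common dispersion, NB exact test and BH FDR, with an
#' optional visible low-abundance filter (features below `min_cpm`
#' counts-per-million in fewer than `min_libs` libraries are flagged and not
#' tested).
#'
#' @param table count matrix or [count_table()].
#' @param groups two group labels per library; first level = reference.
#' @param alpha FDR threshold for the `direction` call (default 0.05).
#' @param dispersion optional fixed dispersion overriding the qCML estimate.
#' @param min_cpm,min_libs low-abundance filter: features with at least
#'   `min_cpm` counts-per-million in at least `min_libs` libraries are
#'   tested, the rest flagged. Defaults: 1 CPM in the smallest group size.
#'   Set both to 0 to disable.
#' @return data.table ordered by `fdr` then feature: `feature`, `logFC`,
#'   `logCPM`, `pvalue`, `fdr`, `direction` (`up`/`down`/`ns`), `filtered`.
#' @export
run_de <- function(table, groups = NULL, alpha = 0.05, dispersion = NULL,
                   min_cpm = 1, min_libs = NULL) {
  counts <- .as_counts(table)
  if (ncol(counts) < 2L) stop("need at least 2 libraries", call. = FALSE)
  groups <- .get_groups(counts, if (is.null(groups)) attr(table, "groups")
                                else groups)
  if (is.null(min_libs)) min_libs <- min(table(groups))
  norm <- tmm_factors(counts)
  cpm <- sweep(counts, 2L, colSums(counts) * norm / 1e6, `/`)
  keep <- rowSums(cpm >= min_cpm) >= min_libs
  sub <- counts[keep, , drop = FALSE]
  if (is.null(dispersion))
    dispersion <- estimate_common_dispersion(sub, groups, norm)
  res <- exact_test_nb(sub, groups, norm, dispersion)
  res[, fdr := bh_adjust(pvalue)]
  res[, direction := ifelse(fdr < alpha, ifelse(logFC > 0, "up", "down"),
                            "ns")]
  res[, filtered := FALSE]
  if (any(!keep)) {
    skip <- data.table(feature = rownames(counts)[!keep], logFC = NA_real_,
                       logCPM = NA_real_, pvalue = NA_real_, fdr = NA_real_,
                       direction = "ns", all_zero = NA, filtered = TRUE)
    res <- rbind(res, skip)
  }
  res[, all_zero := NULL]
  setorder(res, fdr, feature, na.last = TRUE)
  attr(res, "dispersion") <- dispersion
  attr(res, "norm_factors") <- norm
  res[]
}

#' Write differential expression results and MA-plot data
#'
#' @param result output of [run_de()].
#' @param path TSV path for the result table.
#' @param ma_path optional TSV path for MA-plot data (logCPM vs logFC with
#'   the significance call).
#' @export
write_de_tsv <- function(result, path, ma_path = NULL) {
  fwrite(result, path, sep = "\t")
  if (!is.null(ma_path))
    fwrite(result[!is.na(pvalue),
                  .(feature, A = logCPM, M = logFC, direction)],
           ma_path, sep = "\t")
  invisible(path)
}
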