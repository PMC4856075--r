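# TSV serialization of count tables, carrying the group labels in a header
# comment line.

#' Write a count table as TSV
#'
#' The first line is a comment of the form
#' `# groups: lib1=wt,lib2=wt,...` carrying the column group labels.
#'
#' @param table a [count_table()].
#' @param path output TSV path.
#' @export
write_count_table <- function(table, path) {
  groups <- attr(table, "groups")
  hdr <- sprintf("# groups: %s",
                 paste(sprintf("%s=%s", colnames(table), groups),
                       collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("feature", colnames(table)), collapse = "\t"), con)
  m <- unclass(table)
  writeLines(paste(rownames(m),
                   apply(m, 1L, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Read a count table written by [write_count_table()]
#'
#' @param path TSV path.
#' @return a [count_table()].
#' @export
read_count_table <- function(path) {
  first <- readLines(path, n = 1L)
  d <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                  check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  groups <- NULL
  if (grepl("^# groups:", first)) {
    kv <- strsplit(strsplit(sub("^# groups: *", "", first), ",")[[1L]], "=")
    groups <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  } else {
    groups <- setNames(rep("all", ncol(m)), colnames(m))
  }
  count_table(m, groups)
}
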