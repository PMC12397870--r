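## Partitioned peptide storage: hive-style directory keys
## (rule / stratum / length / sequence prefix), columnar parquet via arrow
## when available, with a plain delimited fallback writer.

#' Write a peptide mapping table as a hive-partitioned dataset
#'
#' Partition keys are the generation rule, the stratum, the peptide length
#' and the sequence prefix (first residue for tryptic peptides, first two
#' for nonspecific and spliced ones). With `backend = "auto"` the arrow
#' parquet writer is used when the arrow package is installed, otherwise
#' one tab-delimited file per partition is written under the same
#' `key=value` directory layout.
#'
#' @param peptides `data.table` with at least `sequence`, `rule`, `stratum`.
#' @param dir Output directory.
#' @param backend `"auto"`, `"arrow"` or `"delim"`.
#' @param partitioning Partition key columns, outermost first. The deepest
#'   layout also includes `"prefix"`; shallower partitioning avoids
#'   thousands of tiny files on toy-scale data, and `prefix` is always
#'   available as a column.
#' @return Invisibly, `dir`.
#' @export
write_peptide_store <- function(peptides, dir,
                                backend = c("auto", "arrow", "delim"),
                                partitioning = c("rule", "stratum", "length",
                                                 "prefix")) {
  backend <- match.arg(backend)
  dt <- data.table::as.data.table(peptides)
  dt[, length := nchar(sequence)]
  dt[, prefix := peptide_prefix(sequence, rule)]
  if (backend == "auto")
    backend <- if (requireNamespace("arrow", quietly = TRUE)) "arrow" else "delim"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (backend == "arrow") {
    arrow::write_dataset(dt, dir, partitioning = partitioning,
                         format = "parquet", compression = "lz4",
                         max_partitions = 65536L)
  } else {
    parts <- split(dt, by = partitioning)
    for (p in parts) {
      sub <- do.call(file.path, c(list(dir), lapply(partitioning, function(k)
        paste0(k, "=", p[[k]][1]))))
      dir.create(sub, showWarnings = FALSE, recursive = TRUE)
      data.table::fwrite(p, file.path(sub, "part-0.tsv"), sep = "\t")
    }
  }
  invisible(dir)
}

#' Read back a partitioned peptide dataset
#'
#' @param dir Dataset directory written by [write_peptide_store()].
#' @return `data.table` of the union of all partitions.
#' @export
read_peptide_store <- function(dir) {
  pq <- list.files(dir, pattern = "\\.parquet$", recursive = TRUE,
                   full.names = TRUE)
  if (length(pq)) {
    ds <- arrow::open_dataset(dir)
    return(data.table::as.data.table(ds))
  }
  files <- list.files(dir, pattern = "\\.tsv$", recursive = TRUE,
                      full.names = TRUE)
  data.table::rbindlist(lapply(files, data.table::fread), fill = TRUE)
}
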