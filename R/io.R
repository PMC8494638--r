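#' @title Plain-text dataset containers
#' @description Readers and writers for the pipeline's on-disk formats. The
#'   sweep container mirrors an HDF5-style layout in plain text: one TSV per
#'   sweep (columns `voltage_mv`, `current_pa`) plus a JSON sidecar holding
#'   the per-sweep attributes (`sampling_rate_hz`, `stim_start_s`,
#'   `stim_end_s`, `stim_amplitude_pa`, `bridge_mohm`, `bias_pa`).
#' @name containers
NULL

#' @rdname containers
#' @param sweeps List of [new_sweep()]s.
#' @param dir Output directory (created if needed).
#' @return `write_sweep_set`: `dir`, invisibly. `read_sweep_set`: a list of
#'   [new_sweep()]s.
#' @export
write_sweep_set <- function(sweeps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  attrs <- lapply(seq_along(sweeps), function(i) {
    sw <- sweeps[[i]]
    f <- sprintf("sweep_%03d.tsv", i)
    utils::write.table(
      data.frame(voltage_mv = sw$voltage, current_pa = sw$current),
      file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
    list(file = f, sampling_rate_hz = sw$sampling_rate,
         stim_start_s = sw$stim_start, stim_end_s = sw$stim_end,
         stim_amplitude_pa = sw$stim_amplitude,
         bridge_mohm = sw$bridge_balance, bias_pa = sw$bias_current)
  })
  jsonlite::write_json(attrs, file.path(dir, "sweeps.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname containers
#' @export
read_sweep_set <- function(dir) {
  attrs <- jsonlite::read_json(file.path(dir, "sweeps.json"))
  lapply(attrs, function(a) {
    d <- utils::read.delim(file.path(dir, a$file))
    new_sweep(d$voltage_mv, as.numeric(d$current_pa),
              as.numeric(a$sampling_rate_hz), as.numeric(a$stim_start_s),
              as.numeric(a$stim_end_s), as.numeric(a$stim_amplitude_pa),
              as.numeric(a$bridge_mohm), as.numeric(a$bias_pa))
  })
}

#' Write an expression set as MatrixMarket + TSV metadata
#'
#' @param es An `expression_set`.
#' @param dir Output directory; receives `matrix.mtx`, `genes.tsv`,
#'   `cells.tsv`.
#' @return `dir`, invisibly.
#' @export
write_expression_set <- function(es, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(es$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(es$gene_meta, file.path(dir, "genes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(es$cell_meta, file.path(dir, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read an expression set written by [write_expression_set()]
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return An `expression_set` (without simulation ground truth).
#' @export
read_expression_set <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  gene_meta <- utils::read.delim(file.path(dir, "genes.tsv"))
  cell_meta <- utils::read.delim(file.path(dir, "cells.tsv"))
  rownames(counts) <- gene_meta$symbol
  colnames(counts) <- cell_meta$cell
  structure(list(counts = counts, gene_meta = gene_meta,
                 cell_meta = cell_meta, truth = NULL),
            class = "expression_set")
}
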