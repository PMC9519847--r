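# Result and container serialization: plain gzip-compressed CSV arrays with a
# JSON sidecar carrying the run metadata, so every figure-level result can be
# regenerated bit-for-bit from (seeds, config).

#' Save a network (connectivity + patterns) to disk
#'
#' Writes the binary connectivity and the pattern matrix as gzip-compressed
#' CSV arrays next to a JSON sidecar holding `N`, `c` (or per-neuron
#' in-degrees online), `p` and any extra metadata such as seeds.
#'
#' @param C a [connectivity()] object.
#' @param patterns a [pattern_set()] (optional).
#' @param path base path without extension; writes `<path>_C.csv.gz`,
#'   `<path>_xi.csv.gz` and `<path>.json`.
#' @param meta named list of extra metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
save_network <- function(C, patterns = NULL, path, meta = list()) {
  C <- as_connectivity(C)
  write_gz_array(C$C, paste0(path, "_C.csv.gz"))
  sidecar <- c(list(N = C$N, mode = C$mode, in_degree = C$in_degree), meta)
  if (!is.null(patterns)) {
    patterns <- as_pattern_set(patterns)
    write_gz_array(patterns$xi, paste0(path, "_xi.csv.gz"))
    sidecar$p <- patterns$p
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a network saved by [save_network()]
#'
#' @param path base path used at save time.
#' @return List with `C` ([connectivity()]), `patterns` ([pattern_set()] or
#'   `NULL`) and `meta` (the JSON sidecar contents).
#' @export
load_network <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  C <- connectivity(read_gz_array(paste0(path, "_C.csv.gz")),
                    mode = if (identical(meta$mode, "online")) "online" else "offline")
  xi_path <- paste0(path, "_xi.csv.gz")
  patterns <- if (file.exists(xi_path)) pattern_set(read_gz_array(xi_path)) else NULL
  list(C = C, patterns = patterns, meta = meta)
}

write_gz_array <- function(M, file) {
  con <- gzfile(file, "w")
  on.exit(close(con))
  utils::write.table(M, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(file)
}

read_gz_array <- function(file) {
  M <- as.matrix(utils::read.table(gzfile(file), sep = ","))
  dimnames(M) <- NULL
  M
}

#' Write a sweep summary with a JSON provenance header
#'
#' The records go to `<path>.csv` and the metadata (seeds, configuration) to
#' `<path>.json`; [read_sweep()] restores the records losslessly.
#'
#' @param sweep a `sweep_summary` data frame from [improvement_sweep()].
#' @param path base path without extension.
#' @param meta named list of provenance metadata.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path, meta = list()) {
  utils::write.csv(as.data.frame(sweep), paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sweep summary written by [write_sweep()]
#'
#' @param path base path used at write time.
#' @return List with `sweep` (`sweep_summary` data frame) and `meta`.
#' @export
read_sweep <- function(path) {
  sweep <- utils::read.csv(paste0(path, ".csv"))
  class(sweep) <- c("sweep_summary", "data.frame")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(sweep = sweep, meta = meta)
}

#' Write an online trajectory to CSV
#'
#' @param run an `online_trajectory` from [online_run()].
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(run, file) {
  utils::write.csv(run$trajectory, file, row.names = FALSE)
  invisible(file)
}
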