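#' Read genome sequences from FASTA
#'
#' Sequences are uppercased; ids are the first whitespace-delimited token of
#' each header. Duplicate ids or an empty file are errors.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  stats::setNames(toupper(as.character(seqs)), ids)
}

#' Write genome sequences to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a probe sequence table
#'
#' TSV with columns `probe_id`, `sequence`.
#'
#' @param path TSV file.
#' @return validated probe table data.frame.
#' @export
read_probe_table <- function(path) {
  validate_probe_table(read_tsv(path, colClasses = "character"))
}

#' @rdname read_probe_table
#' @param probes probe table data.frame.
#' @export
write_probe_table <- function(probes, path) {
  write_tsv(validate_probe_table(probes), path)
}

#' Read/write the three-tier mapping table
#'
#' TSV with columns `probe_id`, `probeset_id`, `transcript_cluster_id`;
#' duplicate rows collapse to one association.
#'
#' @param path TSV file.
#' @return a [mapping_table()].
#' @export
read_mapping <- function(path) {
  mapping_table(read_tsv(path, colClasses = "character"))
}

#' @rdname read_mapping
#' @param mapping a [mapping_table()].
#' @export
write_mapping <- function(mapping, path) {
  write_tsv(as.data.frame(mapping), path)
}

#' Read/write an expression matrix
#'
#' TSV with the row id in the first column and sample ids in the header.
#' Values are written at full precision so round trips are lossless.
#'
#' @param path TSV file.
#' @return numeric matrix with row and column names.
#' @export
read_matrix <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 1L) stop("matrix file has no columns: ", path)
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  if (nrow(df) == 0L)
    return(matrix(numeric(0), nrow = 0L, ncol = ncol(vals),
                  dimnames = list(NULL, names(vals))))
  bad <- which(!vapply(vals, is.numeric, TRUE))
  if (length(bad))
    stop("non-numeric values in column(s): ",
         paste(names(vals)[bad], collapse = ", "), " of ", path)
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' @rdname read_matrix
#' @param m numeric matrix.
#' @param id_name header for the row-id column (default `"id"`).
#' @export
write_matrix <- function(m, path, id_name = "id") {
  stopifnot(is.matrix(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_name, colnames(m)), collapse = "\t"), con)
  if (nrow(m) > 0L) {
    fm <- matrix(formatC(m, format = "g", digits = 17), nrow = nrow(m))
    body <- paste(rownames(m),
                  apply(fm, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read/write a mask set
#'
#' TSV with columns `cluster_id`, `provenance`; parameters and metadata go to
#' a JSON sidecar (`<path>.json`).
#'
#' @param path TSV file.
#' @return a [mask_set()].
#' @export
read_mask <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  if (!all(c("cluster_id", "provenance") %in% names(df)))
    stop("mask file needs columns cluster_id, provenance")
  side <- paste0(path, ".json")
  extra <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  else list(parameters = list(), metadata = list())
  prov <- if (nrow(df)) df$provenance[1L] else extra$provenance %||% "combined"
  mask_set(df$cluster_id, provenance = prov,
           parameters = as.list(extra$parameters),
           metadata = as.list(extra$metadata))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_mask
#' @param mask a [mask_set()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_set"))
  write_tsv(data.frame(cluster_id = mask$cluster_ids,
                       provenance = rep(mask$provenance,
                                        length(mask$cluster_ids)),
                       stringsAsFactors = FALSE), path)
  jsonlite::write_json(list(provenance = mask$provenance,
                            parameters = mask$parameters,
                            metadata = mask$metadata),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Read a two-column sample annotation (sample_id, label)
#'
#' Used for group and batch assignments.
#'
#' @param path TSV with columns `sample_id` and one label column.
#' @return named character vector label\[sample_id\].
#' @export
read_groups <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  if (ncol(df) < 2L || names(df)[1L] != "sample_id")
    stop("groups file needs columns sample_id, <label>")
  stats::setNames(df[[2L]], df$sample_id)
}

#' Read a JSON run configuration into a simulation config
#'
#' Unknown keys are rejected; values override [simulation_config()] defaults.
#'
#' @param path JSON file of config fields.
#' @return a [simulation_config()].
#' @export
read_sim_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(simulation_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(simulation_config, vals)
}
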