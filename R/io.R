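#' Read and write pipeline tables
#'
#' Plain-text interchange formats: per-scan detection tables (TSV with
#' columns run_id, rt_min, mono_mass_da, charge, area), identification
#' tables (CSV with sequence, charge, mono_mass_da, rt_min, score,
#' accession, run_id), the run manifest (TSV), protein FASTA, and a
#' two-column (term, accession) or GMT annotation table.
#'
#' @param path File path.
#' @return data.table (tables) or named character vector (FASTA).
#' @name silac_io
NULL

#' @rdname silac_io
#' @export
read_detections <- function(path) {
  as.data.table(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname silac_io
#' @param x Table or sequence set to write.
#' @export
write_detections <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname silac_io
#' @export
read_identifications <- function(path) {
  as.data.table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname silac_io
#' @export
write_identifications <- function(x, path) {
  write.table(x, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname silac_io
#' @export
read_manifest <- function(path) {
  as.data.table(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname silac_io
#' @export
write_manifest <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname silac_io
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  # accession = first whitespace-delimited token of the header
  names(out) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1L), 1L)
  out
}

#' @rdname silac_io
#' @param width Line-wrap width for FASTA output.
#' @export
write_fasta <- function(x, path, width = 60L) {
  ss <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' @rdname silac_io
#' @export
read_annotation <- function(path) {
  first <- readLines(path, n = 1L)
  n_fields <- length(strsplit(first, "\t", fixed = TRUE)[[1L]])
  if (n_fields > 2L) {
    # GMT: term, description, accessions...
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    out <- rbindlist(lapply(lines, function(f)
      data.table(term = f[1L], accession = f[-(1:2)])))
  } else {
    out <- as.data.table(read.delim(path, header = FALSE,
                                    stringsAsFactors = FALSE,
                                    col.names = c("term", "accession")))
  }
  out
}

#' Write a simulated experiment to disk
#'
#' Emits the external-interface files of a [simulate_experiment()] result:
#' `detections.tsv`, `identifications.csv`, `manifest.tsv`,
#' `proteome.fasta` and `ground_truth.tsv`.
#'
#' @param sim A `silac_sim`.
#' @param proteome The matching `silac_proteome` (for the FASTA).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_sim <- function(sim, proteome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    detections = file.path(dir, "detections.tsv"),
    ids = file.path(dir, "identifications.csv"),
    manifest = file.path(dir, "manifest.tsv"),
    fasta = file.path(dir, "proteome.fasta"),
    truth = file.path(dir, "ground_truth.tsv")
  )
  write_detections(sim$detections, paths["detections"])
  write_identifications(sim$ids, paths["ids"])
  write_manifest(sim$manifest, paths["manifest"])
  write_fasta(proteome$fasta, paths["fasta"])
  write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
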