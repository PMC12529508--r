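#' Read a proteome FASTA file
#'
#' Parses a (UniProt-style) proteome FASTA into a protein table. Headers of the
#' form \code{sp|ACC|NAME desc} (or \code{tr|...}) yield \code{accession = ACC};
#' plain headers yield the first whitespace-delimited token. Sequences are
#' uppercased and whitespace-stripped.
#'
#' @param path Path to a FASTA file.
#' @param on_nonstandard What to do with sequences containing amino-acid codes
#'   outside the 20 standard ones (B/J/O/U/X/Z or other letters):
#'   \code{"error"} (default) aborts, \code{"skip"} drops the record with a
#'   warning. Residue numbering downstream must be exact, hence the strict
#'   default.
#' @return A \code{data.table} with columns \code{accession},
#'   \code{description}, \code{sequence}; one row per record.
#' @export
read_fasta <- function(path, on_nonstandard = c("error", "skip")) {
  on_nonstandard <- match.arg(on_nonstandard)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("malformed FASTA '", path, "': ",
                                          conditionMessage(e)))
  if (length(aa) == 0L) stop("FASTA file '", path, "' contains no records")
  headers <- names(aa)
  acc <- vapply(headers, parse_fasta_accession, character(1), USE.NAMES = FALSE)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(aa)))
  dup <- acc[duplicated(acc)]
  if (length(dup)) {
    stop("duplicate accession(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs) | !nzchar(seqs)
  if (any(bad)) {
    if (on_nonstandard == "error") {
      stop("non-standard amino-acid code(s) in record(s): ",
           paste(head(acc[bad], 5L), collapse = ", "))
    }
    warning(sum(bad), " record(s) with non-standard residues skipped")
    acc <- acc[!bad]; headers <- headers[!bad]; seqs <- seqs[!bad]
  }
  data.table::data.table(accession = acc, description = headers,
                         sequence = seqs)
}

parse_fasta_accession <- function(header) {
  first <- strsplit(header, "[[:space:]]+")[[1]][1]
  if (grepl("^[a-z]{2}\\|", first)) {
    strsplit(first, "\\|")[[1]][2]
  } else {
    first
  }
}

#' Write a protein table to FASTA
#'
#' @param proteome \code{data.table} as returned by [read_fasta()] or
#'   [generate_proteome()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  stopifnot(all(c("accession", "sequence") %in% names(proteome)))
  aa <- Biostrings::AAStringSet(proteome$sequence)
  names(aa) <- proteome$accession
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
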