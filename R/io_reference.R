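#' Read a reference cysteine-site database
#'
#' Reads a CSV/TSV with columns \code{cysteineid}, \code{identified},
#' \code{ligandable} (booleans as 0/1/true/false), emulating a community
#' reference of previously identified and liganded cysteines (CysDB-style).
#' A site flagged ligandable must also be flagged identified.
#'
#' @param path Path to a comma- or tab-delimited file with a header row.
#' @return \code{data.table} keyed by \code{cysteineid} with logical columns
#'   \code{identified} and \code{ligandable}.
#' @export
read_reference_db <- function(path) {
  if (!file.exists(path)) stop("reference database not found: ", path)
  dt <- data.table::fread(path, header = TRUE, colClasses = "character")
  need <- c("cysteineid", "identified", "ligandable")
  names(dt) <- tolower(names(dt))
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("reference database missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ids <- trimws(dt$cysteineid)
  # validates the "ACC_C<int>(_C<int>)*" grammar; errors on malformed ids
  lapply(ids, parse_site_id)
  identified <- parse_flag(dt$identified, "identified")
  ligandable <- parse_flag(dt$ligandable, "ligandable")
  bad <- ligandable & !identified
  if (any(bad)) {
    stop("reference database invariant violated (ligandable but not ",
         "identified) for: ", paste(head(ids[bad], 5L), collapse = ", "))
  }
  out <- data.table::data.table(cysteineid = ids, identified = identified,
                                ligandable = ligandable)
  if (anyDuplicated(out$cysteineid)) {
    stop("duplicate cysteineid in reference database: ",
         out$cysteineid[duplicated(out$cysteineid)][1])
  }
  data.table::setkey(out, cysteineid)
  out
}

parse_flag <- function(x, col) {
  x <- tolower(trimws(x))
  val <- rep(NA, length(x))
  val[x %in% c("1", "true", "t", "yes")] <- TRUE
  val[x %in% c("0", "false", "f", "no")] <- FALSE
  if (anyNA(val)) {
    stop("unparseable boolean '", x[is.na(val)][1], "' in column '", col, "'")
  }
  val
}
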