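# Labeled-PSM table reading: canonical columns, a ColumnMap indirection for
# search-engine exports, and the modification-string dialect "<pos><AA>(<delta>)".

#' Canonical column map for PSM tables
#'
#' The pipeline's canonical field names, mapped to the input table's headers.
#' Override entries to adapt e.g. a FragPipe-style psm.tsv export without
#' hard-coding a vendor schema.
#'
#' @param ... Named overrides, canonical name = input header
#'   (e.g. \code{peptide = "Peptide"}).
#' @return Named character vector mapping canonical names to column headers.
#'   Canonical names: \code{peptide}, \code{assigned_modifications},
#'   \code{protein}, \code{intensity_l}, \code{intensity_h}, \code{condition},
#'   \code{replicate}, and optional \code{localized}.
#' @export
default_column_map <- function(...) {
  cm <- c(peptide = "peptide",
          assigned_modifications = "assigned_modifications",
          protein = "protein",
          intensity_l = "intensity_l",
          intensity_h = "intensity_h",
          condition = "condition",
          replicate = "replicate",
          localized = "localized")
  ov <- c(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(cm))
    if (length(unknown)) stop("unknown canonical field(s): ",
                              paste(unknown, collapse = ", "))
    cm[names(ov)] <- ov
  }
  cm
}

#' Parse an assigned-modifications string
#'
#' Dialect: semicolon-separated \code{"<pos><AA>(<delta>)"} entries, e.g.
#' \code{"1C(463.2366); 4C(57.02146)"}. Position is 1-based within the peptide.
#'
#' @param mods Character vector of modification strings ("" or NA = none).
#' @param peptides Optional character vector of peptide sequences; when given,
#'   each modification position is checked to point at the stated residue.
#' @return A list (one element per input) of data.frames with columns
#'   \code{position}, \code{aa}, \code{delta}.
#' @export
parse_modifications <- function(mods, peptides = NULL) {
  out <- vector("list", length(mods))
  for (i in seq_along(mods)) {
    m <- mods[i]
    if (is.na(m) || !nzchar(trimws(m))) {
      out[[i]] <- data.frame(position = integer(), aa = character(),
                             delta = numeric())
      next
    }
    parts <- trimws(strsplit(m, ";", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    hit <- regmatches(parts, regexec("^([0-9]+)([A-Za-z])\\(([-0-9.]+)\\)$", parts))
    bad <- vapply(hit, length, integer(1)) != 4L
    if (any(bad)) stop("unparseable modification entry: '", parts[bad][1], "'")
    pos <- vapply(hit, function(h) as.integer(h[2]), integer(1))
    aa <- vapply(hit, function(h) toupper(h[3]), character(1))
    delta <- vapply(hit, function(h) as.numeric(h[4]), numeric(1))
    if (!is.null(peptides)) {
      pep <- peptides[i]
      if (any(pos < 1L | pos > nchar(pep))) {
        stop("modification position out of range for peptide '", pep, "'")
      }
      res <- substring(pep, pos, pos)
      if (any(res != aa)) {
        stop("modification residue mismatch in peptide '", pep, "': expected ",
             paste(aa[res != aa], collapse = ","), " at position ",
             paste(pos[res != aa], collapse = ","))
      }
    }
    out[[i]] <- data.frame(position = pos, aa = aa, delta = delta)
  }
  out
}

#' Read a labeled-PSM quantification table
#'
#' Reads a TSV of quantified, probe-labeled PSMs (one row per PSM) using a
#' [default_column_map()] to resolve headers. Rows with both MS1 intensities
#' missing or zero are unquantified: they are dropped and counted in the load
#' report (attribute \code{"dropped"}). Channel membership is \emph{not}
#' decided here (see [assign_channel()]): in MS1 label quantification both
#' channels of a pair share one peptide row, with the intensities in
#' \code{intensity_l}/\code{intensity_h}.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param colmap Column map from [default_column_map()].
#' @return \code{data.table} with canonical columns \code{peptide},
#'   \code{assigned_modifications}, \code{protein}, \code{intensity_l},
#'   \code{intensity_h}, \code{condition}, \code{replicate},
#'   \code{localized} (NA when absent from input). Attributes:
#'   \code{dropped} (count of unquantified rows), \code{n_input} (data rows
#'   in the file).
#' @export
read_psm_table <- function(path, colmap = default_column_map()) {
  if (!file.exists(path)) stop("PSM table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL)
  mandatory <- c("peptide", "assigned_modifications", "protein",
                 "intensity_l", "intensity_h", "condition", "replicate")
  missing_cols <- mandatory[!colmap[mandatory] %in% names(dt)]
  if (length(missing_cols)) {
    stop("PSM table '", path, "' is missing mandatory column(s): ",
         paste(colmap[missing_cols], collapse = ", "))
  }
  out <- data.table::data.table(
    peptide = toupper(trimws(dt[[colmap[["peptide"]]]])),
    assigned_modifications = dt[[colmap[["assigned_modifications"]]]],
    protein = trimws(dt[[colmap[["protein"]]]]),
    intensity_l = parse_intensity(dt[[colmap[["intensity_l"]]]],
                                  colmap[["intensity_l"]]),
    intensity_h = parse_intensity(dt[[colmap[["intensity_h"]]]],
                                  colmap[["intensity_h"]]),
    condition = dt[[colmap[["condition"]]]],
    replicate = as.integer(dt[[colmap[["replicate"]]]])
  )
  loc_col <- colmap[["localized"]]
  out$localized <- if (!is.na(loc_col) && loc_col %in% names(dt)) {
    x <- dt[[loc_col]]
    ifelse(nzchar(trimws(x)), x, NA_character_)
  } else NA_character_
  if (anyNA(out$replicate)) {
    stop("non-integer replicate value at data row ",
         which(is.na(out$replicate))[1])
  }
  # validate modification syntax / positions up front
  parse_modifications(out$assigned_modifications, out$peptide)
  unquant <- out$intensity_l <= 0 & out$intensity_h <= 0
  res <- out[!unquant]
  data.table::setattr(res, "dropped", sum(unquant))
  data.table::setattr(res, "n_input", nrow(out))
  res
}

parse_intensity <- function(x, colname) {
  x <- trimws(x)
  val <- suppressWarnings(as.numeric(x))
  val[!nzchar(x)] <- 0
  bad <- is.na(val)
  if (any(bad)) {
    stop("non-numeric value '", x[bad][1], "' in intensity column '", colname,
         "' at data row ", which(bad)[1])
  }
  if (any(val < 0)) {
    stop("negative intensity in column '", colname, "' at data row ",
         which(val < 0)[1])
  }
  val
}
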