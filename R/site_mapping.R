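# Peptide -> cysteine-residue mapping on the protein (UniProt, 1-based)
# coordinate frame, plus isotope-channel classification from modification mass.

CARBAMIDOMETHYL_DELTA <- 57.02146

# MS1 label deltas for the three capture-reagent chemistries.
LABEL_SCHEMES <- list(
  "biotin-azide" = c(light = 463.2366, heavy = 469.2742),
  "isoTOP-TEV"   = c(light = 521.3074, heavy = 527.3213),
  "sCIP"         = c(light = 493.3007, heavy = 499.3145)
)

#' Isotopic label scheme
#'
#' Describes the light/heavy cysteine modification masses of an enrichment
#' reagent chemistry. Three presets cover the common reagents: heavy/light
#' biotin azide, TEV-cleavable isoTOP tags, and sCIP tags.
#'
#' @param name One of \code{"biotin-azide"}, \code{"isoTOP-TEV"},
#'   \code{"sCIP"}.
#' @param light_delta,heavy_delta Override the preset masses (Da).
#' @param match_tolerance Absolute tolerance (Da) when matching a modification
#'   delta to a label mass. Default 0.01 Da (~20 ppm at these masses).
#' @return A \code{label_scheme} list with fields \code{name},
#'   \code{light_delta}, \code{heavy_delta}, \code{carbamidomethyl_delta},
#'   \code{match_tolerance}.
#' @export
label_scheme <- function(name = c("biotin-azide", "isoTOP-TEV", "sCIP"),
                         light_delta = NULL, heavy_delta = NULL,
                         match_tolerance = 0.01) {
  name <- match.arg(name)
  preset <- LABEL_SCHEMES[[name]]
  light <- light_delta %||% unname(preset["light"])
  heavy <- heavy_delta %||% unname(preset["heavy"])
  if (!(heavy > light) || light <= 0) {
    stop("label scheme requires 0 < light_delta < heavy_delta")
  }
  if (match_tolerance <= 0 || match_tolerance >= (heavy - light) / 2) {
    stop("match_tolerance must be in (0, (heavy_delta - light_delta)/2)")
  }
  structure(list(name = name, light_delta = light, heavy_delta = heavy,
                 carbamidomethyl_delta = CARBAMIDOMETHYL_DELTA,
                 match_tolerance = match_tolerance),
            class = "label_scheme")
}

#' Locate a peptide within a protein sequence
#'
#' Exact substring matching (no mismatches, I/L distinct); all occurrences,
#' including overlapping ones, in ascending order.
#'
#' @param peptide Peptide sequence (non-empty).
#' @param sequence Protein sequence.
#' @return Integer vector of 1-based start offsets (possibly empty).
#' @export
locate_peptide <- function(peptide, sequence) {
  stopifnot(nzchar(peptide))
  if (nchar(peptide) > nchar(sequence)) return(integer(0))
  m <- Biostrings::matchPattern(peptide, Biostrings::AAString(sequence))
  sort(Biostrings::start(m))
}

#' Render a cysteine site identifier
#'
#' Grammar \code{"ACC_C<p1>(_C<p2>)*"}: UniProtKB accession plus the 1-based
#' protein residue number(s) of the modified cysteine(s). Peptides with several
#' cysteines and no localization render all of them (the modification is not
#' attributable to one).
#'
#' @param accession Protein accession.
#' @param positions Strictly increasing 1-based cysteine residue positions.
#' @return The identifier string.
#' @export
render_site_id <- function(accession, positions) {
  stopifnot(length(positions) >= 1L, !is.unsorted(positions, strictly = TRUE))
  paste0(accession, "_", paste0("C", positions, collapse = "_"))
}

#' Parse a cysteine site identifier
#'
#' @param id Identifier string in the [render_site_id()] grammar.
#' @return List with \code{accession} and integer \code{positions}.
#' @export
parse_site_id <- function(id) {
  if (!grepl("^.+_C[0-9]+(_C[0-9]+)*$", id)) {
    stop("malformed cysteine site identifier: '", id, "'")
  }
  m <- regmatches(id, regexpr("(_C[0-9]+)+$", id))
  accession <- substr(id, 1L, nchar(id) - nchar(m))
  positions <- as.integer(strsplit(sub("^_C", "", m), "_C", fixed = TRUE)[[1]])
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("site identifier positions not strictly increasing: '", id, "'")
  }
  list(accession = accession, positions = positions)
}

#' Cysteine site for a located peptide
#'
#' Converts a peptide occurrence into a residue identifier: protein position =
#' start + peptide index - 1 for each reported cysteine. With upstream
#' localization only the localized positions are reported (unambiguous);
#' otherwise all cysteines in the peptide, ambiguous when more than one.
#'
#' @param peptide Peptide sequence containing at least one \code{C}.
#' @param start 1-based start offset from [locate_peptide()].
#' @param accession Protein accession.
#' @param localized Optional integer vector of localized cysteine positions
#'   (1-based, within the peptide).
#' @return List with \code{site} (rendered id), \code{accession},
#'   \code{positions} (protein frame), \code{ambiguous}.
#' @export
cysteine_site <- function(peptide, start, accession, localized = NULL) {
  cys <- which(strsplit(peptide, "", fixed = TRUE)[[1]] == "C")
  if (!length(cys)) stop("peptide '", peptide, "' contains no cysteine")
  if (!is.null(localized) && length(localized)) {
    localized <- sort(unique(as.integer(localized)))
    if (!all(localized %in% cys)) {
      stop("localized position(s) not cysteines of peptide '", peptide, "'")
    }
    pos <- start + localized - 1L
    ambiguous <- FALSE
  } else {
    pos <- start + cys - 1L
    ambiguous <- length(cys) > 1L
  }
  list(site = render_site_id(accession, pos), accession = accession,
       positions = pos, ambiguous = ambiguous)
}

#' Classify a PSM's modification channel
#'
#' A PSM is \code{probe-labeled} when at least one cysteine modification delta
#' is within tolerance of the scheme's light or heavy label mass (the channel
#' itself lives in the two intensity columns: both channels of an MS1 pair
#' share one peptide row); \code{carbamidomethyl-only} when all cysteine
#' modifications match +57.02146; otherwise \code{unlabeled} (with a warning
#' when a cysteine delta matches none of the three masses).
#'
#' @param peptide Peptide sequence.
#' @param modifications Modification string (see [parse_modifications()]) or a
#'   parsed data.frame.
#' @param scheme A [label_scheme()].
#' @return One of \code{"probe-labeled"}, \code{"carbamidomethyl-only"},
#'   \code{"unlabeled"}.
#' @export
assign_channel <- function(peptide, modifications, scheme) {
  mods <- if (is.data.frame(modifications)) modifications
          else parse_modifications(modifications, peptide)[[1]]
  if (!nrow(mods)) return("unlabeled")
  res <- substring(peptide, mods$position, mods$position)
  cys <- mods$delta[res == "C"]
  if (!length(cys)) return("unlabeled")
  tol <- scheme$match_tolerance
  is_probe <- abs(cys - scheme$light_delta) <= tol |
              abs(cys - scheme$heavy_delta) <= tol
  is_cam <- abs(cys - scheme$carbamidomethyl_delta) <= tol
  if (any(is_probe)) return("probe-labeled")
  if (all(is_cam)) return("carbamidomethyl-only")
  if (any(!is_cam)) {
    warning("cysteine modification delta ", cys[!is_cam][1],
            " matches no known label mass; PSM treated as unlabeled")
  }
  "unlabeled"
}

#' Map probe-labeled PSMs to cysteine site identifiers
#'
#' Classifies each PSM's channel, locates its peptide in the assigned protein,
#' and renders the residue identifier. PSMs are excluded (and tallied by
#' reason) when they are not probe-labeled, their accession is absent from the
#' proteome, their peptide is not found in the assigned protein, or the
#' peptide occurs at more than one offset (residue numbers would be
#' ambiguous).
#'
#' @param psms PSM table from [read_psm_table()].
#' @param proteome Protein table from [read_fasta()].
#' @param scheme A [label_scheme()].
#' @return The mapped subset of \code{psms} with added columns \code{site},
#'   \code{start}, \code{ambiguous}. Attribute \code{"mapping_report"}: named
#'   integer counts per exclusion reason (\code{carbamidomethyl-only},
#'   \code{unlabeled}, \code{missing-protein}, \code{peptide-not-found},
#'   \code{multi-locus}).
#' @export
map_psms <- function(psms, proteome, scheme) {
  stopifnot(inherits(scheme, "label_scheme"))
  report <- c("carbamidomethyl-only" = 0L, "unlabeled" = 0L,
              "missing-protein" = 0L, "peptide-not-found" = 0L,
              "multi-locus" = 0L)
  seqs <- proteome$sequence
  names(seqs) <- proteome$accession

  n <- nrow(psms)
  site <- character(n); start <- integer(n); ambiguous <- logical(n)
  keep <- logical(n)
  mods_parsed <- parse_modifications(psms$assigned_modifications, psms$peptide)
  # cache peptide locations per (protein, peptide)
  loc_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    chan <- assign_channel(psms$peptide[i], mods_parsed[[i]], scheme)
    if (chan != "probe-labeled") {
      report[[chan]] <- report[[chan]] + 1L
      next
    }
    acc <- psms$protein[i]
    if (is.na(seqs[acc])) {
      report[["missing-protein"]] <- report[["missing-protein"]] + 1L
      next
    }
    key <- paste0(acc, "\r", psms$peptide[i])
    hits <- if (!is.null(loc_cache[[key]])) loc_cache[[key]] else {
      h <- locate_peptide(psms$peptide[i], seqs[[acc]])
      loc_cache[[key]] <- h
      h
    }
    if (length(hits) == 0L) {
      report[["peptide-not-found"]] <- report[["peptide-not-found"]] + 1L
      next
    }
    if (length(hits) > 1L) {
      report[["multi-locus"]] <- report[["multi-locus"]] + 1L
      next
    }
    loc <- psms$localized[i]
    loc <- if (!is.na(loc) && nzchar(loc)) {
      as.integer(strsplit(loc, "[;,]")[[1]])
    } else NULL
    cs <- cysteine_site(psms$peptide[i], hits[1], acc, loc)
    site[i] <- cs$site; start[i] <- hits[1]; ambiguous[i] <- cs$ambiguous
    keep[i] <- TRUE
  }
  out <- psms[keep]
  out[, `:=`(site = site[keep], start = start[keep],
             ambiguous = ambiguous[keep])]
  data.table::setattr(out, "mapping_report", report)
  out
}
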