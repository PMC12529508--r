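# Report writing. All reports are UTF-8 tab-delimited with a header row,
# log2 ratios rendered to 4 decimals and missing ratio cells as "N.D.".

#' Write analysis reports
#'
#' Emits the screen's result tables into \code{outdir}:
#' \itemize{
#'   \item \code{site_table.tsv} — one row per site x condition with
#'     per-replicate log2 ratios (\code{ratio_rep<k>} columns), mean, SD,
#'     n_psms, ambiguity flag and call;
#'   \item \code{compound_summary.tsv} — per-condition reactivity;
#'   \item \code{stereo_comparison.tsv} (optional);
#'   \item \code{reference_categories.tsv} (optional);
#'   \item \code{dose_matrix.tsv} (optional).
#' }
#'
#' @param called Table from [call_sites()].
#' @param quants Replicate-level table from [quantify_sites()].
#' @param compound_summary Table from [summarize_compound()].
#' @param outdir Output directory (created if needed).
#' @param stereo Optional table from [stereo_compare()].
#' @param reference Optional table from [categorize_vs_reference()].
#' @param dose Optional table from [dose_response_table()].
#' @return Named character vector of written paths, invisibly.
#' @export
write_reports <- function(called, quants, compound_summary, outdir,
                          stereo = NULL, reference = NULL, dose = NULL) {
  if (nrow(called) == 0L) stop("no results to report")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(site_table = file.path(outdir, "site_table.tsv"),
             compound_summary = file.path(outdir, "compound_summary.tsv"))

  reps <- sort(unique(quants$replicate))
  wide <- data.table::dcast(quants, site + condition ~ replicate,
                            value.var = "log2_ratio")
  data.table::setnames(wide, as.character(reps), paste0("ratio_rep", reps))
  site_tab <- merge(called, wide, by = c("site", "condition"), all.x = TRUE)
  data.table::setorder(site_tab, site, condition)
  rep_cols <- paste0("ratio_rep", reps)
  out <- site_tab[, c("site", "condition", rep_cols, "mean_log2", "sd_log2",
                      "n_replicates_quantified", "n_psms", "ambiguous",
                      "call"), with = FALSE]
  for (cc in c(rep_cols, "mean_log2", "sd_log2")) {
    data.table::set(out, j = cc, value = format_ratio(out[[cc]]))
  }
  data.table::fwrite(out, paths["site_table"], sep = "\t", quote = FALSE)

  cs <- data.table::copy(compound_summary)
  cs[, fraction_liganded := sprintf("%.4f", fraction_liganded)]
  data.table::fwrite(cs, paths["compound_summary"], sep = "\t", quote = FALSE)

  if (!is.null(stereo)) {
    paths["stereo_comparison"] <- file.path(outdir, "stereo_comparison.tsv")
    st <- data.table::copy(stereo)
    for (cc in c("mean_a", "mean_b", "delta")) {
      data.table::set(st, j = cc, value = format_ratio(st[[cc]]))
    }
    st[, p_value := sprintf("%.6g", p_value)]
    data.table::fwrite(st, paths["stereo_comparison"], sep = "\t",
                       quote = FALSE)
  }
  if (!is.null(reference)) {
    paths["reference_categories"] <- file.path(outdir,
                                               "reference_categories.tsv")
    data.table::fwrite(reference, paths["reference_categories"], sep = "\t",
                       quote = FALSE)
  }
  if (!is.null(dose)) {
    paths["dose_matrix"] <- file.path(outdir, "dose_matrix.tsv")
    dm <- data.table::copy(dose)
    for (cc in setdiff(names(dm), "site")) {
      data.table::set(dm, j = cc, value = format_ratio(dm[[cc]]))
    }
    data.table::fwrite(dm, paths["dose_matrix"], sep = "\t", quote = FALSE)
  }
  invisible(paths)
}

#' Write a mapping/exclusion report
#'
#' @param report Named integer vector (attribute \code{"mapping_report"} of
#'   [map_psms()]).
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_mapping_report <- function(report, path) {
  data.table::fwrite(data.table::data.table(reason = names(report),
                                            count = as.integer(report)),
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}
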