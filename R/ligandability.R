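# Ligandability calling and screen-level analytics.
#
# Calling rule: a site x condition is liganded when its mean Log2(H/L) is at
# or above the threshold (default 2) AND, when the replicate SD exceeds the SD
# gate (default 2), every replicate ratio must itself clear the threshold.
# Anti-ligandable mirrors the rule at the negative threshold (compound-induced
# increase in probe labeling).

#' Calling configuration
#'
#' @param threshold Log2(H/L) ligandability threshold (> 0), default 2.
#' @param sd_gate Replicate-SD value above which every replicate must clear
#'   the threshold (default 2).
#' @param anti_threshold Anti-ligandability threshold (< 0), default -2.
#' @param excluded_compounds Condition names excluded from screen totals
#'   (promiscuously reactive compounds, e.g. \code{c("SO56", "SO59")}).
#' @param required_replicates Minimum quantified replicates, default 2.
#' @return A \code{call_config} list.
#' @export
call_config <- function(threshold = 2, sd_gate = 2, anti_threshold = -2,
                        excluded_compounds = character(),
                        required_replicates = 2L) {
  stopifnot(threshold > 0, sd_gate > 0, anti_threshold < 0,
            required_replicates >= 1L)
  structure(list(threshold = threshold, sd_gate = sd_gate,
                 anti_threshold = anti_threshold,
                 excluded_compounds = as.character(excluded_compounds),
                 required_replicates = as.integer(required_replicates)),
            class = "call_config")
}

#' Call ligandability for merged site results
#'
#' Applies the two-clause rule to every quantified row of a
#' [merge_replicates()] table. Rows already marked \code{unquantified} are
#' left untouched.
#'
#' @param merged Table from [merge_replicates()].
#' @param cfg A [call_config()].
#' @return \code{merged} with the \code{call} column set to one of
#'   \code{liganded}, \code{anti-liganded}, \code{not-liganded},
#'   \code{unquantified}.
#' @export
call_sites <- function(merged, cfg = call_config()) {
  stopifnot(inherits(cfg, "call_config"))
  out <- data.table::copy(merged)
  q <- out$call != "unquantified"
  # single-replicate groups (required_replicates = 1) have no SD: gate passes
  sd_ok <- is.na(out$sd_log2) | out$sd_log2 <= cfg$sd_gate
  lig <- out$mean_log2 >= cfg$threshold &
    (sd_ok | out$min_rep >= cfg$threshold)
  anti <- out$mean_log2 <= cfg$anti_threshold &
    (sd_ok | out$max_rep <= cfg$anti_threshold)
  out[q, call := ifelse(lig[q], "liganded",
                 ifelse(anti[q], "anti-liganded", "not-liganded"))]
  out[]
}

#' Single site-condition ligandability call
#'
#' Scalar convenience form of [call_sites()] operating on replicate ratios
#' directly; used heavily in tests.
#'
#' @param ratios Numeric vector of replicate log2(H/L) ratios.
#' @param cfg A [call_config()].
#' @return \code{"liganded"}, \code{"anti-liganded"}, \code{"not-liganded"}
#'   or \code{"unquantified"}.
#' @export
call_site <- function(ratios, cfg = call_config()) {
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) < cfg$required_replicates) return("unquantified")
  m <- mean(ratios)
  s <- if (length(ratios) >= 2L) sd(ratios) else NA_real_
  sd_ok <- is.na(s) || s <= cfg$sd_gate
  if (m >= cfg$threshold && (sd_ok || min(ratios) >= cfg$threshold)) {
    "liganded"
  } else if (m <= cfg$anti_threshold &&
             (sd_ok || max(ratios) <= cfg$anti_threshold)) {
    "anti-liganded"
  } else {
    "not-liganded"
  }
}

#' Anti-ligandability predicate
#'
#' @inheritParams call_site
#' @return TRUE when the site is called anti-liganded.
#' @export
call_antiligandable <- function(ratios, cfg = call_config()) {
  identical(call_site(ratios, cfg), "anti-liganded")
}

#' Per-compound reactivity summary
#'
#' For each condition: sites identified (quantified), sites liganded, and the
#' liganded fraction — the screen's per-compound reactivity readout.
#'
#' @param called Table from [call_sites()].
#' @param cfg A [call_config()] (supplies the exclusion list).
#' @return \code{data.table}: \code{condition}, \code{n_identified},
#'   \code{n_liganded}, \code{n_anti_liganded}, \code{fraction_liganded},
#'   \code{excluded_from_totals}.
#' @export
summarize_compound <- function(called, cfg = call_config()) {
  out <- called[, .(
    n_identified = sum(call != "unquantified"),
    n_liganded = sum(call == "liganded"),
    n_anti_liganded = sum(call == "anti-liganded")
  ), by = condition]
  out[, fraction_liganded := ifelse(n_identified == 0, 0,
                                    n_liganded / n_identified)]
  out[, excluded_from_totals := condition %in% cfg$excluded_compounds]
  data.table::setorder(out, condition)
  out[]
}

#' Screen-level unique totals
#'
#' Unique quantified cysteines and proteins over the whole screen, plus the
#' total ligandable cysteines: sites liganded by at least one non-excluded
#' condition (set semantics, each site counted once).
#'
#' @param called Table from [call_sites()].
#' @param cfg A [call_config()].
#' @return List: \code{n_unique_sites}, \code{n_unique_proteins},
#'   \code{n_liganded_total}.
#' @export
screen_totals <- function(called, cfg = call_config()) {
  quant <- called[call != "unquantified"]
  sites <- unique(quant$site)
  proteins <- unique(vapply(sites, function(s) parse_site_id(s)$accession,
                            character(1)))
  lig <- unique(quant[call == "liganded" &
                        !condition %in% cfg$excluded_compounds]$site)
  list(n_unique_sites = length(sites),
       n_unique_proteins = length(proteins),
       n_liganded_total = length(lig))
}

#' Categorise quantified sites against a reference database
#'
#' Each quantified site is \code{known-ligandable} (in the reference with the
#' ligandable flag), \code{known-identified-only}, or \code{novel} (absent).
#' The liganded-and-novel subset is reported separately: newly ligandable
#' cysteines not previously captured by the reference.
#'
#' @param called Table from [call_sites()].
#' @param refdb Table from [read_reference_db()].
#' @return \code{data.table} (\code{site}, \code{category}, \code{liganded})
#'   with attribute \code{"summary"}: named counts per category plus
#'   \code{liganded_novel}.
#' @export
categorize_vs_reference <- function(called, refdb) {
  quant <- called[call != "unquantified"]
  per_site <- quant[, .(liganded = any(call == "liganded")), by = site]
  idx <- match(per_site$site, refdb$cysteineid)
  category <- ifelse(is.na(idx), "novel",
              ifelse(refdb$ligandable[idx], "known-ligandable",
                     "known-identified-only"))
  out <- data.table::data.table(site = per_site$site, category = category,
                                liganded = per_site$liganded)
  data.table::setorder(out, site)
  smry <- c(`known-ligandable` = sum(category == "known-ligandable"),
            `known-identified-only` = sum(category == "known-identified-only"),
            novel = sum(category == "novel"),
            liganded_novel = sum(out$liganded & category == "novel"))
  data.table::setattr(out, "summary", smry)
  out[]
}

#' Hit-rate analysis against a reference database
#'
#' Per condition: the fraction of its liganded sites that are
#' reference-ligandable (higher fractions flag promiscuously liganded,
#' well-trodden cysteines). Per site: the number of conditions liganding it
#' out of the total conditions screened (dose points count as separate
#' conditions).
#'
#' @param called Table from [call_sites()].
#' @param refdb Table from [read_reference_db()].
#' @return List of two tables: \code{per_condition} (\code{condition},
#'   \code{n_liganded}, \code{refdb_fraction}; fraction NA when a condition
#'   liganded nothing) and \code{per_site} (\code{site},
#'   \code{n_conditions_liganding}, \code{total_conditions}).
#' @export
hit_rate_analysis <- function(called, refdb) {
  total_conditions <- length(unique(called$condition))
  ref_lig <- refdb$cysteineid[refdb$ligandable]
  per_condition <- called[, .(
    n_liganded = sum(call == "liganded"),
    refdb_fraction = {
      lig <- site[call == "liganded"]
      if (length(lig)) mean(lig %in% ref_lig) else NA_real_
    }
  ), by = condition]
  data.table::setorder(per_condition, condition)
  per_site <- called[call != "unquantified",
                     .(n_conditions_liganding = sum(call == "liganded"),
                       total_conditions = total_conditions),
                     by = site]
  data.table::setorder(per_site, site)
  list(per_condition = per_condition[], per_site = per_site[])
}

#' Stereoselectivity comparison of two conditions
#'
#' Compares replicate log2(H/L) ratios between two conditions (typically a
#' stereoisomer pair at matched concentration) per site: the mean difference
#' (fold-change difference of the log2 ratios) and a two-sample
#' unequal-variance (Welch) t-test p-value. A site is selective for A when
#' \code{delta >= min_delta} and \code{p < alpha} (B symmetric). Sites lacking
#' two replicates on either side are skipped and tallied.
#'
#' @param quants Replicate-level table from [quantify_sites()].
#' @param condition_a,condition_b The two condition names.
#' @param min_delta Minimum |mean difference| for selectivity, default 1.
#' @param alpha Significance level, default 0.05.
#' @param adjust P-value adjustment method (\code{"none"} default, or any
#'   \code{stats::p.adjust} method such as \code{"BH"}); selectivity uses the
#'   adjusted values.
#' @return \code{data.table}: \code{site}, \code{mean_a}, \code{mean_b},
#'   \code{delta}, \code{p_value}, \code{selective_for} (\code{A}/\code{B}/
#'   \code{none}). Attribute \code{"skipped"}: named counts
#'   (\code{missing-in-one}, \code{too-few-replicates}).
#' @export
stereo_compare <- function(quants, condition_a, condition_b,
                           min_delta = 1, alpha = 0.05, adjust = "none") {
  qa <- quants[condition == condition_a]
  qb <- quants[condition == condition_b]
  sites_a <- unique(qa$site); sites_b <- unique(qb$site)
  shared <- sort(intersect(sites_a, sites_b))
  skipped <- c("missing-in-one" =
                 length(union(sites_a, sites_b)) - length(shared),
               "too-few-replicates" = 0L)
  rows <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    s <- shared[i]
    a <- qa[site == s]$log2_ratio
    b <- qb[site == s]$log2_ratio
    if (length(a) < 2L || length(b) < 2L) {
      skipped[["too-few-replicates"]] <- skipped[["too-few-replicates"]] + 1L
      next
    }
    rows[[i]] <- data.table::data.table(
      site = s, mean_a = mean(a), mean_b = mean(b),
      delta = mean(a) - mean(b), p_value = welch_p(a, b))
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0L) {
    out <- data.table::data.table(site = character(), mean_a = numeric(),
                                  mean_b = numeric(), delta = numeric(),
                                  p_value = numeric(),
                                  selective_for = character())
    data.table::setattr(out, "skipped", skipped)
    return(out[])
  }
  p_eff <- p.adjust(out$p_value, method = adjust)
  out[, selective_for := ifelse(delta >= min_delta & p_eff < alpha, "A",
                         ifelse(-delta >= min_delta & p_eff < alpha, "B",
                                "none"))]
  data.table::setorder(out, site)
  data.table::setattr(out, "skipped", skipped)
  out[]
}

# Welch two-sample p-value with degenerate-variance handling: identical
# constant samples -> 1 (no evidence), separated constant samples -> 0.
welch_p <- function(a, b) {
  if (sd(a) == 0 && sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  t.test(a, b, var.equal = FALSE)$p.value
}

#' Parse a condition name in the dose grammar
#'
#' Conditions encode dose as \code{"name@<conc><unit>"}
#' (e.g. \code{"BEH-1-Sa@5uM"}); plain names have no concentration.
#'
#' @param condition Character vector of condition names.
#' @return \code{data.table}: \code{condition}, \code{compound},
#'   \code{concentration} (numeric, NA when undosed), \code{unit}.
#' @export
parse_condition <- function(condition) {
  m <- regmatches(condition,
                  regexec("^(.*)@([0-9]*\\.?[0-9]+)([A-Za-z]+)$", condition))
  has_at <- grepl("@", condition, fixed = TRUE)
  ok <- vapply(m, length, integer(1)) == 4L
  if (any(has_at & !ok)) {
    stop("unparseable concentration in condition '",
         condition[has_at & !ok][1], "' (expected name@<conc><unit>)")
  }
  data.table::data.table(
    condition = condition,
    compound = ifelse(ok, vapply(m, function(x) if (length(x)) x[2] else NA_character_,
                                 character(1)), condition),
    concentration = ifelse(ok, vapply(m, function(x) if (length(x)) as.numeric(x[3]) else NA_real_,
                                      numeric(1)), NA_real_),
    unit = ifelse(ok, vapply(m, function(x) if (length(x)) x[4] else NA_character_,
                             character(1)), NA_character_)
  )
}

#' Dose-response matrix for dosed conditions
#'
#' Builds a site x condition matrix of mean log2(H/L) ratios across the
#' concentration range of one or more compounds (heatmap-style). Columns are
#' ordered by compound then ascending concentration; rows by decreasing
#' maximum |mean| so the strongest targets lead. Unquantified cells are NA
#' (rendered "N.D." in reports).
#'
#' @param called Table from [call_sites()] (or [merge_replicates()]).
#' @param compounds Optional compound names to include; default every dosed
#'   compound present.
#' @return \code{data.table} with a \code{site} column plus one numeric column
#'   per condition.
#' @export
dose_response_table <- function(called, compounds = NULL) {
  info <- parse_condition(unique(called$condition))
  dosed <- info[!is.na(concentration)]
  if (!is.null(compounds)) dosed <- dosed[compound %in% compounds]
  if (nrow(dosed) == 0L) stop("no dosed conditions (name@<conc><unit>) found")
  data.table::setorder(dosed, compound, concentration)
  sub <- called[condition %in% dosed$condition & call != "unquantified"]
  if (nrow(sub) == 0L) stop("no quantified sites for the dosed conditions")
  wide <- data.table::dcast(sub, site ~ condition, value.var = "mean_log2")
  cols <- dosed$condition[dosed$condition %in% names(wide)]
  data.table::setcolorder(wide, c("site", cols))
  strength <- apply(as.matrix(wide[, ..cols]), 1L,
                    function(r) max(abs(r), na.rm = TRUE))
  wide <- wide[order(-strength, site)]
  wide[]
}
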