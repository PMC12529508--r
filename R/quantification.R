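# Per-site log2(H/L) competition ratios: PSM-level ratios with capping,
# robust aggregation to site x condition x replicate, and replicate merging.
#
# H = heavy = vehicle (DMSO), L = light = compound. A high log2(H/L) means the
# compound blocked probe labeling at the site (competition).

#' PSM-level log2(H/L) ratio with capping
#'
#' The raw heavy/light intensity ratio is clamped into \code{[1/cap, cap]}
#' before taking log2: complete competition gives a zero light intensity and
#' an otherwise infinite ratio. Vectorised.
#'
#' @param light,heavy Non-negative MS1 intensities (not both zero).
#' @param cap Ratio cap (> 1); default 20, the convention in competitive
#'   isoTOP-ABPP work.
#' @return \code{data.table} with columns \code{log2_ratio} and \code{capped}.
#' @export
psm_log2_ratio <- function(light, heavy, cap = 20) {
  stopifnot(cap > 1, length(light) == length(heavy))
  if (any(light < 0 | heavy < 0)) stop("negative intensity")
  if (any(light == 0 & heavy == 0)) {
    stop("both intensities zero: unquantified PSM should have been dropped ",
         "at read time")
  }
  ratio <- ifelse(light == 0, Inf, heavy / light)
  clamped <- pmin(pmax(ratio, 1 / cap), cap)
  data.table::data.table(log2_ratio = log2(clamped),
                         capped = clamped != ratio)
}

#' Quantify mapped PSMs per site, condition and replicate
#'
#' Computes PSM-level capped log2(H/L) ratios and aggregates them within each
#' site x condition x replicate group. The default summary is the median
#' (robust to outlier PSMs); \code{capped} is TRUE when the median-selecting
#' value(s) were capped.
#'
#' @param mapped Mapped PSM table from [map_psms()].
#' @param cap Ratio cap passed to [psm_log2_ratio()].
#' @param aggregate \code{"median"} (default) or \code{"mean"}.
#' @return \code{data.table}: \code{site}, \code{condition}, \code{replicate},
#'   \code{log2_ratio}, \code{n_psms}, \code{capped}, \code{ambiguous}.
#' @export
quantify_sites <- function(mapped, cap = 20, aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(nrow(mapped) >= 1L)
  pr <- psm_log2_ratio(mapped$intensity_l, mapped$intensity_h, cap = cap)
  dt <- data.table::data.table(site = mapped$site,
                               condition = mapped$condition,
                               replicate = mapped$replicate,
                               ambiguous = mapped$ambiguous,
                               log2_ratio = pr$log2_ratio,
                               capped = pr$capped)
  agg_fun <- if (aggregate == "median") aggregate_median else aggregate_mean
  out <- dt[, agg_fun(log2_ratio, capped),
            by = .(site, condition, replicate, ambiguous)]
  data.table::setorder(out, site, condition, replicate)
  out[]
}

# median with the midpoint convention for even n; capped iff a median-selecting
# value was capped
aggregate_median <- function(x, capped) {
  o <- order(x)
  n <- length(x)
  sel <- unique(c(floor((n + 1) / 2), ceiling((n + 1) / 2)))
  list(log2_ratio = mean(x[o][sel]), n_psms = n,
       capped = any(capped[o][sel]))
}

aggregate_mean <- function(x, capped) {
  list(log2_ratio = mean(x), n_psms = length(x), capped = any(capped))
}

#' Merge replicate quantifications per site and condition
#'
#' A site x condition needs ratios in at least \code{required_replicates}
#' replicates to be quantified (default 2: "both replicates"); otherwise it is
#' \code{unquantified} with mean/SD absent. SD is the sample (n-1) estimator.
#' The call column is set to \code{"pending"} for quantified rows and filled
#' by [call_sites()].
#'
#' @param quants Replicate-level table from [quantify_sites()].
#' @param required_replicates Minimum replicates with a ratio (default 2).
#' @return \code{data.table}: \code{site}, \code{condition},
#'   \code{n_replicates_quantified}, \code{mean_log2}, \code{sd_log2},
#'   \code{min_rep}, \code{max_rep}, \code{n_psms}, \code{ambiguous},
#'   \code{call}.
#' @export
merge_replicates <- function(quants, required_replicates = 2L) {
  stopifnot(required_replicates >= 1L)
  dup <- quants[, .N, by = .(site, condition, replicate)][N > 1L]
  if (nrow(dup)) {
    stop("duplicate replicate index for site ", dup$site[1], ", condition ",
         dup$condition[1])
  }
  out <- quants[, {
    n <- .N
    # mean is defined from one replicate on, SD from two; the quantified /
    # unquantified status is carried by the call column alone
    list(n_replicates_quantified = n,
         mean_log2 = mean(log2_ratio),
         sd_log2 = if (n >= 2L) sd(log2_ratio) else NA_real_,
         min_rep = min(log2_ratio),
         max_rep = max(log2_ratio),
         n_psms = sum(n_psms),
         ambiguous = any(ambiguous),
         call = if (n >= required_replicates) "pending" else "unquantified")
  }, by = .(site, condition)]
  data.table::setorder(out, site, condition)
  out[]
}
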