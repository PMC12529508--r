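# Synthetic competitive chemoproteomic screens: proteome generation, in-silico
# tryptic digestion, and labeled-PSM tables with planted ground-truth effects.
#
# The generator emulates the statistical structure the analysis assumes:
# tryptic cysteine peptides carrying probe label masses, log-normal MS1
# abundances, per-site true log2(H/L) effects (0 for background, >0 for
# liganded), replicate noise, PSM multiplicity and missingness. It does not
# emulate spectra, retention time, FDR/decoys, or plate-position effects.

# Monoisotopic residue masses (Da) for the 20 standard amino acids.
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
WATER_MASS <- 18.010565

# Average proteome amino-acid frequencies (Swiss-Prot-like), used as the
# default residue distribution for synthetic proteins; Cys is overridden by
# the configured cysteine frequency and the rest renormalised.
AA_FREQ <- c(
  A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137, Q = 0.0393,
  E = 0.0672, G = 0.0708, H = 0.0227, I = 0.0591, L = 0.0965, K = 0.0580,
  M = 0.0241, F = 0.0386, P = 0.0475, S = 0.0665, T = 0.0536, W = 0.0110,
  Y = 0.0292, V = 0.0686
)

#' Tryptic digestion rules
#'
#' Strict trypsin: cleave after K or R, never when the next residue is P.
#' Peptides must satisfy missed-cleavage, length and (unmodified,
#' monoisotopic) mass windows — the defaults mirror common search settings.
#'
#' @param max_missed_cleavages Maximum internal cleavage sites, default 2.
#' @param min_length,max_length Peptide length window, default 7 to 50.
#' @param min_mass,max_mass Monoisotopic mass window (Da), default 500 to 5000.
#' @return A \code{digest_rules} list.
#' @export
digest_rules <- function(max_missed_cleavages = 2L, min_length = 7L,
                         max_length = 50L, min_mass = 500, max_mass = 5000) {
  stopifnot(min_length < max_length, min_mass < max_mass,
            max_missed_cleavages >= 0L)
  structure(list(max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 min_mass = min_mass, max_mass = max_mass),
            class = "digest_rules")
}

#' Monoisotopic peptide mass
#'
#' Sum of standard monoisotopic residue masses plus one water (18.010565 Da);
#' the unmodified peptide mass.
#'
#' @param peptide Character vector of peptide sequences.
#' @return Numeric vector of masses (Da).
#' @export
peptide_mass <- function(peptide) {
  vapply(peptide, function(p) {
    res <- strsplit(p, "", fixed = TRUE)[[1]]
    m <- RESIDUE_MASS[res]
    if (anyNA(m)) stop("non-standard residue in peptide '", p, "'")
    sum(m) + WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

#' In-silico tryptic digest
#'
#' Enumerates all peptides with at most \code{max_missed_cleavages} internal
#' cleavage sites under the strict-trypsin rule and filters by the length and
#' mass windows.
#'
#' @param sequence Protein sequence.
#' @param rules A [digest_rules()].
#' @return \code{data.table}: \code{peptide}, \code{start} (1-based offset),
#'   \code{missed_cleavages}.
#' @export
digest <- function(sequence, rules = digest_rules()) {
  stopifnot(inherits(rules, "digest_rules"))
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  # cleavage after position i: K/R at i, next residue not P
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | res[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n else integer(0))
  bounds <- unique(bounds)
  k <- length(bounds)
  out <- list()
  for (i in seq_len(k - 1L)) {
    jmax <- min(i + 1L + rules$max_missed_cleavages, k)
    for (j in (i + 1L):jmax) {
      start <- bounds[i] + 1L
      end <- bounds[j]
      len <- end - start + 1L
      if (len < rules$min_length || len > rules$max_length) next
      pep <- substr(sequence, start, end)
      mass <- peptide_mass(pep)
      if (mass < rules$min_mass || mass > rules$max_mass) next
      out[[length(out) + 1L]] <- list(peptide = pep, start = start,
                                      missed_cleavages = j - i - 1L)
    }
  }
  if (!length(out)) {
    return(data.table::data.table(peptide = character(), start = integer(),
                                  missed_cleavages = integer()))
  }
  data.table::rbindlist(out)
}

#' Simulation configuration
#'
#' The stated world of the synthetic screen: two biological replicates per
#' condition, background site effects N(0, sigma_bg), per-PSM replicate noise
#' N(0, sigma_rep), log-normal MS1 abundances, PSM multiplicity
#' Uniform\{1..psm_max\}, and per-PSM missingness. All randomness derives from
#' \code{seed} through keyed streams, so adding conditions does not perturb
#' existing draws.
#'
#' @param seed Mandatory integer seed.
#' @param n_proteins Number of synthetic proteins, default 50.
#' @param length_range Protein length range, default c(100, 600).
#' @param cys_freq Cysteine residue frequency, default 0.0137 (proteome-like).
#' @param conditions Character vector of condition names.
#' @param replicates Replicates per condition, default 2.
#' @param sigma_bg Background true-effect SD, default 0.25.
#' @param sigma_rep Per-PSM replicate noise SD, default 0.30.
#' @param abundance_meanlog,abundance_sdlog Log-normal MS1 abundance
#'   parameters, default meanlog = ln(1e6), sdlog = 1.
#' @param psm_max PSM multiplicity is Uniform\{1..psm_max\}, default 3.
#' @param missingness Per-PSM drop probability, default 0.10.
#' @param localized_prob Probability that a multi-cysteine peptide's label is
#'   localized to a single cysteine, default 0.5.
#' @param planted Optional \code{data.frame(site, condition, effect)} of true
#'   log2(H/L) effects; see [plant_effects()].
#' @param scheme A [label_scheme()] whose light mass the probe carries.
#' @param rules A [digest_rules()].
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(seed, n_proteins = 50L, length_range = c(100L, 600L),
                       cys_freq = 0.0137, conditions = "KB2",
                       replicates = 2L, sigma_bg = 0.25, sigma_rep = 0.30,
                       abundance_meanlog = log(1e6), abundance_sdlog = 1,
                       psm_max = 3L, missingness = 0.10,
                       localized_prob = 0.5, planted = NULL,
                       scheme = label_scheme("biotin-azide"),
                       rules = digest_rules()) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    stop("sim_config requires an integer seed")
  }
  stopifnot(n_proteins >= 1L, length(length_range) == 2L,
            length_range[1] <= length_range[2],
            cys_freq >= 0, cys_freq < 1,
            replicates >= 1L, sigma_bg >= 0, sigma_rep >= 0,
            psm_max >= 1L, missingness >= 0, missingness <= 1,
            localized_prob >= 0, localized_prob <= 1,
            inherits(scheme, "label_scheme"), inherits(rules, "digest_rules"))
  if (!is.null(planted)) {
    stopifnot(all(c("site", "condition", "effect") %in% names(planted)))
  }
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range), cys_freq = cys_freq,
                 conditions = conditions, replicates = as.integer(replicates),
                 sigma_bg = sigma_bg, sigma_rep = sigma_rep,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 psm_max = as.integer(psm_max), missingness = missingness,
                 localized_prob = localized_prob,
                 planted = if (is.null(planted)) NULL
                           else data.table::as.data.table(planted),
                 scheme = scheme, rules = rules),
            class = "sim_config")
}

#' Generate a synthetic proteome
#'
#' Residues drawn i.i.d. from the proteome-average frequency table with the
#' cysteine frequency overridden by \code{cfg$cys_freq}; accessions
#' \code{SYN0001, SYN0002, ...}. Deterministic for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @return Protein table as from [read_fasta()].
#' @export
generate_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  freq <- AA_FREQ
  freq["C"] <- cfg$cys_freq
  others <- setdiff(names(freq), "C")
  freq[others] <- freq[others] / sum(freq[others]) * (1 - cfg$cys_freq)
  seqs <- character(cfg$n_proteins)
  with_seed_(mix_seed(cfg$seed, "proteome"), {
    for (i in seq_len(cfg$n_proteins)) {
      len <- sample(cfg$length_range[1]:cfg$length_range[2], 1L)
      seqs[i] <- paste(sample(names(freq), len, replace = TRUE, prob = freq),
                       collapse = "")
    }
  })
  acc <- sprintf("SYN%04d", seq_len(cfg$n_proteins))
  data.table::data.table(accession = acc,
                         description = paste(acc, "synthetic protein"),
                         sequence = seqs)
}

#' Enumerate mappable cysteine sites of a proteome
#'
#' Digests every protein and keeps cysteine-containing peptides that occur at
#' exactly one offset within their protein (the mapper excludes multi-locus
#' peptides). The localization decision for multi-cysteine peptides is made
#' here, once per peptide, with a keyed RNG — so the site identifiers equal
#' those the analysis pipeline will produce.
#'
#' @param proteome Protein table.
#' @param cfg A [sim_config()].
#' @return \code{data.table}: \code{accession}, \code{peptide}, \code{start},
#'   \code{site}, \code{localized} (peptide-frame position string or NA),
#'   \code{n_cys}.
#' @export
enumerate_sites <- function(proteome, cfg) {
  rows <- list()
  for (i in seq_len(nrow(proteome))) {
    acc <- proteome$accession[i]
    seqc <- proteome$sequence[i]
    dg <- digest(seqc, cfg$rules)
    if (nrow(dg) == 0L) next
    dg <- dg[grepl("C", peptide, fixed = TRUE)]
    if (nrow(dg) == 0L) next
    for (j in seq_len(nrow(dg))) {
      pep <- dg$peptide[j]
      hits <- locate_peptide(pep, seqc)
      if (length(hits) != 1L) next   # mapper would exclude as multi-locus
      cys <- which(strsplit(pep, "", fixed = TRUE)[[1]] == "C")
      localized <- NA_character_
      if (length(cys) > 1L && cfg$localized_prob > 0) {
        localized <- with_seed_(mix_seed(cfg$seed, "loc", acc, pep), {
          if (runif(1) < cfg$localized_prob) {
            as.character(sample(cys, 1L))
          } else NA_character_
        })
      }
      loc_vec <- if (!is.na(localized)) as.integer(localized) else NULL
      cs <- cysteine_site(pep, dg$start[j], acc, loc_vec)
      rows[[length(rows) + 1L]] <- list(accession = acc, peptide = pep,
                                        start = dg$start[j], site = cs$site,
                                        localized = localized,
                                        n_cys = length(cys))
    }
  }
  if (!length(rows)) {
    return(data.table::data.table(accession = character(),
                                  peptide = character(), start = integer(),
                                  site = character(), localized = character(),
                                  n_cys = integer()))
  }
  data.table::rbindlist(rows)
}

#' Plant true effects on a fraction of sites
#'
#' Samples \code{fraction} of the proteome's mappable site identifiers (keyed
#' RNG) and assigns \code{effect} as the true log2(H/L) ratio for every listed
#' condition.
#'
#' @param proteome Protein table.
#' @param cfg A [sim_config()].
#' @param fraction Fraction of unique sites to plant, default 0.10.
#' @param effect Planted log2(H/L) effect, default 3.
#' @param conditions Conditions to plant on, default all of
#'   \code{cfg$conditions}.
#' @return \code{data.table}: \code{site}, \code{condition}, \code{effect}.
#' @export
plant_effects <- function(proteome, cfg, fraction = 0.10, effect = 3,
                          conditions = cfg$conditions) {
  sites <- unique(enumerate_sites(proteome, cfg)$site)
  n_pick <- max(1L, round(fraction * length(sites)))
  picked <- with_seed_(mix_seed(cfg$seed, "plant"),
                       sort(sample(sites, n_pick)))
  data.table::CJ(site = picked, condition = conditions)[
    , .(site, condition, effect = effect)]
}

#' Generate a synthetic labeled-PSM screen
#'
#' For every mappable cysteine peptide x condition x replicate the generator
#' draws a PSM count, drops PSMs with the missingness probability, and writes
#' one row per surviving PSM with heavy = abundance (vehicle) and
#' light = abundance x 2^-observed so that log2(H/L) recovers the observed
#' ratio. The true site effect is the planted value or N(0, sigma_bg), shared
#' by all peptides mapping to the site; per-PSM noise is N(0, sigma_rep).
#'
#' @param proteome Protein table from [generate_proteome()] (or any protein
#'   table).
#' @param cfg A [sim_config()].
#' @return List: \code{psms} (canonical-dialect PSM table),
#'   \code{ground_truth} (\code{site}, \code{condition}, \code{true_effect},
#'   \code{liganded} at the Log2(H/L) >= 2 rule), \code{sites} (the
#'   [enumerate_sites()] table).
#' @export
generate_screen <- function(proteome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sitetab <- enumerate_sites(proteome, cfg)
  if (nrow(sitetab) == 0L) stop("digest yields no cysteine peptides")
  if (!is.null(cfg$planted)) {
    orphan <- setdiff(cfg$planted$site, sitetab$site)
    if (length(orphan)) {
      stop("planted site(s) absent from digestible peptides: ",
           paste(head(orphan, 5L), collapse = ", "))
    }
  }
  planted_key <- if (!is.null(cfg$planted)) {
    stats::setNames(cfg$planted$effect,
                    paste(cfg$planted$site, cfg$planted$condition, sep = "\r"))
  } else numeric(0)

  # true effect per unique site x condition (shared across peptides)
  usites <- unique(sitetab$site)
  truth <- data.table::CJ(site = usites, condition = cfg$conditions,
                          sorted = TRUE)
  truth[, true_effect := {
    key <- paste(site, condition, sep = "\r")
    pl <- planted_key[key]
    ifelse(!is.na(pl), pl,
           vapply(key, function(k) {
             if (cfg$sigma_bg == 0) 0 else {
               sc <- strsplit(k, "\r", fixed = TRUE)[[1]]
               with_seed_(mix_seed(cfg$seed, "bg", sc[1], sc[2]),
                          rnorm(1, 0, cfg$sigma_bg))
             }
           }, numeric(1)))
  }]
  truth[, liganded := true_effect >= 2]
  effect_key <- stats::setNames(truth$true_effect,
                                paste(truth$site, truth$condition, sep = "\r"))

  light_delta <- cfg$scheme$light_delta
  heavy_delta <- cfg$scheme$heavy_delta
  rows <- list()
  for (i in seq_len(nrow(sitetab))) {
    pep <- sitetab$peptide[i]
    acc <- sitetab$accession[i]
    cys <- which(strsplit(pep, "", fixed = TRUE)[[1]] == "C")
    mod_pos <- if (!is.na(sitetab$localized[i])) {
      as.integer(sitetab$localized[i])
    } else cys[1]
    for (cond in cfg$conditions) {
      r <- effect_key[[paste(sitetab$site[i], cond, sep = "\r")]]
      for (rep in seq_len(cfg$replicates)) {
        grp <- with_seed_(mix_seed(cfg$seed, "psm", acc, pep, cond, rep), {
          n_psm <- sample.int(cfg$psm_max, 1L)
          keep <- runif(n_psm) >= cfg$missingness
          obs <- rep(r, n_psm) + (if (cfg$sigma_rep == 0) 0 else
                                    rnorm(n_psm, 0, cfg$sigma_rep))
          ab <- rlnorm(n_psm, cfg$abundance_meanlog, cfg$abundance_sdlog)
          chan_light <- runif(n_psm) < 0.5
          list(keep = keep, obs = obs, ab = ab, chan_light = chan_light)
        })
        if (!any(grp$keep)) next
        k <- which(grp$keep)
        delta <- ifelse(grp$chan_light[k], light_delta, heavy_delta)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          peptide = pep,
          assigned_modifications = sprintf("%dC(%.4f)", mod_pos, delta),
          protein = acc,
          intensity_l = grp$ab[k] * 2^(-grp$obs[k]),
          intensity_h = grp$ab[k],
          condition = cond,
          replicate = rep,
          localized = sitetab$localized[i]
        )
      }
    }
  }
  psms <- data.table::rbindlist(rows)
  if (nrow(psms) == 0L) {
    warning("missingness removed every PSM: empty screen")
    psms <- data.table::data.table(peptide = character(),
                                   assigned_modifications = character(),
                                   protein = character(),
                                   intensity_l = numeric(),
                                   intensity_h = numeric(),
                                   condition = character(),
                                   replicate = integer(),
                                   localized = character())
  }
  list(psms = psms, ground_truth = truth[], sites = sitetab)
}

#' Write a synthetic screen to disk
#'
#' Emits \code{proteome.fasta}, \code{psms.tsv} (the canonical PSM dialect)
#' and \code{ground_truth.tsv} into \code{outdir}. Byte-identical for a fixed
#' configuration.
#'
#' @param proteome Protein table.
#' @param screen List from [generate_screen()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_screen <- function(proteome, screen, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(proteome = file.path(outdir, "proteome.fasta"),
             psms = file.path(outdir, "psms.tsv"),
             ground_truth = file.path(outdir, "ground_truth.tsv"))
  write_fasta(proteome, paths["proteome"])
  psms <- data.table::copy(screen$psms)
  # 17 significant digits: doubles round-trip exactly through the TSV
  psms[, `:=`(intensity_l = sprintf("%.17g", intensity_l),
              intensity_h = sprintf("%.17g", intensity_h),
              localized = ifelse(is.na(localized), "", localized))]
  data.table::fwrite(psms, paths["psms"], sep = "\t", quote = FALSE)
  gt <- data.table::copy(screen$ground_truth)
  gt[, true_effect := sprintf("%.6f", true_effect)]
  data.table::fwrite(gt, paths["ground_truth"], sep = "\t", quote = FALSE)
  invisible(paths)
}
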