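# Shared fixtures and independent oracles. All fixtures are built in code.

write_fasta_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# canonical-dialect PSM TSV from a data.frame
write_psm_file <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  cols <- c("peptide", "assigned_modifications", "protein", "intensity_l",
            "intensity_h", "condition", "replicate", "localized")
  for (cc in setdiff(cols, names(df))) df[[cc]] <- ""
  df <- df[cols]
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  path
}

# a tiny two-protein proteome used across modules
tiny_proteome <- function() {
  data.table::data.table(
    accession = c("P1", "P2"),
    description = c("P1 test", "P2 test"),
    sequence = c("MKCALCRGGKAAAR", "MMWNCPKRCALCR")
  )
}

# --- independent oracles ---------------------------------------------------

# brute-force substring scan over every offset
oracle_locate <- function(peptide, sequence) {
  n <- nchar(sequence); m <- nchar(peptide)
  if (m > n) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - m + 1L)) {
    if (substr(sequence, i, i + m - 1L) == peptide) hits <- c(hits, i)
  }
  hits
}

# brute-force digest: enumerate all (start, end) windows and keep those whose
# bounds sit on cleavage boundaries with <= mm internal cleavage sites and
# that satisfy the length and mass windows
oracle_digest <- function(sequence, mm = 2L, min_len = 7L, max_len = 50L,
                          min_mass = 500, max_mass = 5000) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  is_cut <- function(i) {
    i >= 1L && i < n && res[i] %in% c("K", "R") && res[i + 1L] != "P"
  }
  out <- list()
  for (start in 1:n) {
    for (end in start:n) {
      if (!(start == 1L || is_cut(start - 1L))) next
      if (!(end == n || is_cut(end))) next
      internal <- sum(vapply(start:(end - 1L), function(i) {
        i >= start && i < end && is_cut(i)
      }, logical(1)))
      if (end == start) internal <- 0L
      if (internal > mm) next
      len <- end - start + 1L
      if (len < min_len || len > max_len) next
      pep <- paste(res[start:end], collapse = "")
      mass <- oracle_mass(pep)
      if (mass < min_mass || mass > max_mass) next
      out[[length(out) + 1L]] <- list(peptide = pep, start = start)
    }
  }
  df <- data.frame(peptide = vapply(out, `[[`, character(1), "peptide"),
                   start = vapply(out, `[[`, integer(1), "start"))
  df[order(df$start, nchar(df$peptide)), , drop = FALSE]
}

# independent monoisotopic mass table (transcribed separately from R/)
oracle_mass <- function(pep) {
  tab <- c(A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
           C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
           H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
           M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
           T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)
  sum(tab[strsplit(pep, "")[[1]]]) + 18.010565
}

# direct transcription of the two-clause calling rule: mean >= 2 is the
# primary criterion; when the replicate SD exceeds 2 every replicate must
# itself be >= 2. Anti mirrors at -2.
oracle_call <- function(r1, r2, thr = 2, gate = 2, anti = -2) {
  m <- mean(c(r1, r2))
  s <- stats::sd(c(r1, r2))
  if (m >= thr) {
    if (s <= gate) return("liganded")
    if (r1 >= thr && r2 >= thr) return("liganded")
    return("not-liganded")
  }
  if (m <= anti) {
    if (s <= gate) return("anti-liganded")
    if (r1 <= anti && r2 <= anti) return("anti-liganded")
    return("not-liganded")
  }
  "not-liganded"
}

# random amino-acid sequence (20 standard codes)
random_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# run the analysis pipeline in memory on a generated screen
run_pipeline <- function(proteome, screen, cfg_call = call_config(),
                         scheme = label_scheme("biotin-azide")) {
  mapped <- map_psms(screen$psms, proteome, scheme)
  quants <- quantify_sites(mapped)
  merged <- merge_replicates(quants,
                             required_replicates = cfg_call$required_replicates)
  called <- call_sites(merged, cfg_call)
  list(mapped = mapped, quants = quants, called = called)
}
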