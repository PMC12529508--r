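test_that("locate_peptide finds all occurrences including overlaps", {
  expect_equal(locate_peptide("CALCR", "MKCALCRGGK"), 3L)
  expect_equal(locate_peptide("GG", "GGAGG"), c(1L, 4L))
  expect_equal(locate_peptide("WWW", "MKCALCR"), integer(0))
  expect_equal(locate_peptide("AA", "AAA"), c(1L, 2L))
})

test_that("locate_peptide agrees with brute-force scan on random cases", {
  withr::local_seed(42)
  for (i in 1:1000) {
    seqc <- random_seq(sample(20:80, 1))
    # half the cases: a true substring; half: a random (likely absent) peptide
    pep <- if (i %% 2 == 0) {
      st <- sample(nchar(seqc) - 6L, 1)
      substr(seqc, st, st + sample(3:6, 1))
    } else {
      random_seq(sample(2:6, 1))
    }
    expect_identical(locate_peptide(pep, seqc), oracle_locate(pep, seqc))
  }
})

test_that("site identifiers render and parse as a bijection", {
  cases <- list(list(acc = "P12345", pos = 123L),
                list(acc = "SYN0001", pos = c(3L, 6L, 41L)),
                list(acc = "Q9Y2X7", pos = c(1L, 2L)))
  for (cs in cases) {
    id <- render_site_id(cs$acc, cs$pos)
    back <- parse_site_id(id)
    expect_equal(back$accession, cs$acc)
    expect_equal(back$positions, cs$pos)
  }
  expect_equal(render_site_id("P1", c(3L, 6L)), "P1_C3_C6")
  expect_error(parse_site_id("P12345_123"), "malformed")
  expect_error(render_site_id("P1", c(6L, 3L)))
})

test_that("cysteine_site maps peptide indices to protein coordinates", {
  s <- cysteine_site("CALCR", 3L, "P1")
  expect_equal(s$site, "P1_C3_C6")
  expect_true(s$ambiguous)
  s2 <- cysteine_site("CALCR", 3L, "P1", localized = 1L)
  expect_equal(s2$site, "P1_C3")
  expect_false(s2$ambiguous)
  expect_equal(cysteine_site("ACDK", 10L, "P1")$site, "P1_C11")
  expect_error(cysteine_site("ADEK", 1L, "P1"), "no cysteine")
  expect_error(cysteine_site("CALCR", 3L, "P1", localized = 2L), "localized")
})

test_that("assign_channel classifies label masses per scheme", {
  sch <- label_scheme("biotin-azide")
  expect_equal(assign_channel("CALCR", "1C(463.2366)", sch), "probe-labeled")
  expect_equal(assign_channel("CALCR", "1C(469.2742)", sch), "probe-labeled")
  expect_equal(assign_channel("CALCR", "1C(57.0215)", sch),
               "carbamidomethyl-only")
  # isoTOP-TEV mass under the biotin-azide scheme: warned, unlabeled
  expect_warning(ch <- assign_channel("CALCR", "1C(521.3074)", sch),
                 "no known label")
  expect_equal(ch, "unlabeled")
  # non-Cys modification only
  expect_equal(assign_channel("MCALK", "1M(15.9949)", sch), "unlabeled")
  # scheme presets carry the documented masses
  expect_equal(label_scheme("isoTOP-TEV")$light_delta, 521.3074)
  expect_equal(label_scheme("sCIP")$heavy_delta, 499.3145)
  expect_error(label_scheme("biotin-azide", match_tolerance = 10), "tolerance")
})

test_that("map_psms maps, excludes and tallies with conservation", {
  proteome <- tiny_proteome()
  psms <- data.table::data.table(
    peptide = c("CALCR",        # maps: P1 start 3 -> P1_C3_C6
                "CALCR",        # carbamidomethyl-only
                "CALCR",        # unknown accession
                "CWWK",         # probe-labeled but absent from its protein
                "ACDK"),        # no cysteine mod -> unlabeled
    assigned_modifications = c("1C(463.2366)", "1C(57.02146)", "1C(463.2366)",
                               "1C(463.2366)", ""),
    protein = c("P1", "P1", "P9", "P1", "P1"),
    intensity_l = 100, intensity_h = 200,
    condition = "KB2", replicate = 1L, localized = NA_character_
  )
  mapped <- map_psms(psms, proteome, label_scheme("biotin-azide"))
  rep <- attr(mapped, "mapping_report")
  expect_equal(nrow(mapped), 1L)
  expect_equal(mapped$site, "P1_C3_C6")
  expect_true(mapped$ambiguous)
  expect_equal(rep[["carbamidomethyl-only"]], 1L)
  expect_equal(rep[["unlabeled"]], 1L)
  expect_equal(rep[["missing-protein"]], 1L)
  expect_equal(rep[["peptide-not-found"]], 1L)
  # mapped + excluded = total PSM count (conservation)
  expect_equal(nrow(mapped) + sum(rep), nrow(psms))
  # every reported residue is a cysteine
  seqs <- setNames(proteome$sequence, proteome$accession)
  for (i in seq_len(nrow(mapped))) {
    ps <- parse_site_id(mapped$site[i])
    expect_true(all(substring(seqs[ps$accession], ps$positions,
                              ps$positions) == "C"))
  }
})

test_that("map_psms excludes multi-locus peptides", {
  proteome <- data.table::data.table(
    accession = "P3", description = "P3",
    sequence = "MKCALCRGGCALCRK"   # CALCR at 3 and 10
  )
  psms <- data.table::data.table(
    peptide = "CALCR", assigned_modifications = "1C(463.2366)",
    protein = "P3", intensity_l = 10, intensity_h = 20,
    condition = "KB2", replicate = 1L, localized = NA_character_
  )
  mapped <- map_psms(psms, proteome, label_scheme("biotin-azide"))
  expect_equal(nrow(mapped), 0L)
  expect_equal(attr(mapped, "mapping_report")[["multi-locus"]], 1L)
})
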