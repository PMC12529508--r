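test_that("call_site applies the two-clause rule", {
  cfg <- call_config()
  # mean 2.05 >= 2, sd 0.636 <= 2
  expect_equal(call_site(c(2.5, 1.6), cfg), "liganded")
  # mean 2.75 >= 2 but sd 3.182 > 2 and one replicate < 2
  expect_equal(sd(c(5, 0.5)), 4.5 / sqrt(2))
  expect_equal(call_site(c(5.0, 0.5), cfg), "not-liganded")
  # sd 1.980 just under the gate
  expect_equal(call_site(c(4.9, 2.1), cfg), "liganded")
  # SD > 2 but both replicates clear the threshold
  expect_equal(call_site(c(6.0, 2.1), cfg), "liganded")
  expect_equal(call_site(c(1.0, 1.2), cfg), "not-liganded")
  expect_equal(call_site(2.5, cfg), "unquantified")
})

test_that("anti-ligandability mirrors the rule at the negative threshold", {
  cfg <- call_config()
  expect_true(call_antiligandable(c(-2.5, -2.2), cfg))
  expect_false(call_antiligandable(c(-1.0, -1.2), cfg))
  # sd-gate mirror: mean -2.75 but sd > 2 and one replicate > -2
  expect_false(call_antiligandable(c(-5.0, -0.5), cfg))
  expect_equal(call_site(c(-5.0, -0.5), cfg), "not-liganded")
  expect_equal(call_site(c(-6.0, -2.1), cfg), "anti-liganded")
})

test_that("call monotonicity holds for joint and gate-preserving raises", {
  # NOTE: raising a single replicate is NOT monotone under the SD gate:
  # (2.5, 1.6) is liganded but (7.5, 1.6) is not (SD > 2 and one rep < 2).
  # The rule is monotone under a common shift of all replicates, and under a
  # single-replicate raise that keeps the SD within the gate.
  cfg <- call_config()
  expect_equal(call_site(c(2.5, 1.6), cfg), "liganded")
  expect_equal(call_site(c(7.5, 1.6), cfg), "not-liganded")
  withr::local_seed(10)
  for (i in 1:200) {
    r <- runif(2, -6, 6)
    if (call_site(r, cfg) != "liganded") next
    shift <- runif(1, 0, 3)
    expect_equal(call_site(r + shift, cfg), "liganded")
    up <- r + c(runif(1, 0, 3), 0)
    if (sd(up) <= cfg$sd_gate) expect_equal(call_site(up, cfg), "liganded")
  }
})

test_that("partition: identified = liganded + not-liganded + anti-liganded", {
  cfg <- sim_config(seed = 5, n_proteins = 6, conditions = c("KB2", "SO56"))
  p <- generate_proteome(cfg)
  sc <- generate_screen(p, cfg)
  res <- run_pipeline(p, sc)
  smry <- summarize_compound(res$called, call_config())
  per_cond <- res$called[, .(
    n_q = sum(call != "unquantified"),
    n_parts = sum(call %in% c("liganded", "not-liganded", "anti-liganded"))
  ), by = condition]
  expect_equal(per_cond$n_q, per_cond$n_parts)
  expect_equal(smry[order(condition)]$n_identified,
               per_cond[order(condition)]$n_q)
})

test_that("summarize_compound counts and flags exclusions", {
  called <- data.table::data.table(
    site = sprintf("P1_C%d", 1:100), condition = "SO56",
    call = c(rep("liganded", 23), rep("not-liganded", 77))
  )
  cfg <- call_config(excluded_compounds = c("SO56", "SO59"))
  s <- summarize_compound(called, cfg)
  expect_equal(s$n_identified, 100L)
  expect_equal(s$fraction_liganded, 0.23)
  expect_true(s$excluded_from_totals)
  empty <- summarize_compound(called[call == "none-such"], cfg)
  expect_equal(nrow(empty), 0L)
})

test_that("screen_totals uses set semantics and honours exclusions", {
  called <- data.table::data.table(
    site = c("P1_C3", "P1_C3", "P2_C7", "P3_C9"),
    condition = c("KB2", "KB7", "SO56", "KB2"),
    call = c("liganded", "liganded", "liganded", "not-liganded")
  )
  cfg <- call_config(excluded_compounds = c("SO56", "SO59"))
  t <- screen_totals(called, cfg)
  expect_equal(t$n_unique_sites, 3L)
  expect_equal(t$n_unique_proteins, 3L)
  # P1_C3 liganded twice counts once; P2_C7 liganded only by excluded SO56
  expect_equal(t$n_liganded_total, 1L)
  # exclusion property: dropping the excluded compound's rows changes nothing
  t2 <- screen_totals(called[condition != "SO56"], cfg)
  expect_equal(t2$n_liganded_total, t$n_liganded_total)
  empty <- screen_totals(called[0], cfg)
  expect_equal(empty$n_unique_sites, 0L)
})

ref_fixture <- function() {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c("cysteineid,identified,ligandable",
               "P1_C3,1,1", "P2_C7,1,0"), path)
  read_reference_db(path)
}

test_that("categorize_vs_reference partitions the quantified set", {
  refdb <- ref_fixture()
  called <- data.table::data.table(
    site = c("P1_C3", "P2_C7", "P3_C9"), condition = "KB2",
    call = c("liganded", "not-liganded", "liganded")
  )
  cat <- categorize_vs_reference(called, refdb)
  smry <- attr(cat, "summary")
  expect_equal(unname(smry[c("known-ligandable", "known-identified-only",
                             "novel")]), c(1L, 1L, 1L))
  expect_equal(unname(smry["liganded_novel"]), 1L)
  expect_equal(sort(cat$category),
               sort(c("known-ligandable", "known-identified-only", "novel")))
})

test_that("hit_rate_analysis reports per-condition and per-site rates", {
  refdb <- ref_fixture()
  called <- data.table::data.table(
    site = rep(c("P1_C3", "P3_C9"), 3),
    condition = rep(c("KB2", "KB7", "SO56"), each = 2),
    call = c("liganded", "liganded",   # KB2 ligands both
             "liganded", "not-liganded",
             "not-liganded", "not-liganded")
  )
  hr <- hit_rate_analysis(called, refdb)
  kb2 <- hr$per_condition[condition == "KB2"]
  expect_equal(kb2$refdb_fraction, 0.5)  # P1_C3 in refdb-ligandable, P3_C9 not
  so <- hr$per_condition[condition == "SO56"]
  expect_true(is.na(so$refdb_fraction))  # no liganded sites -> undefined
  ps <- hr$per_site[site == "P1_C3"]
  expect_equal(ps$n_conditions_liganding, 2L)
  expect_equal(ps$total_conditions, 3L)
})

stereo_quants <- function(a, b, cond_a = "Sa", cond_b = "Ra",
                          site = "P1_C3") {
  data.table::rbindlist(list(
    data.table::data.table(site = site, condition = cond_a,
                           replicate = seq_along(a), ambiguous = FALSE,
                           log2_ratio = a, n_psms = 1L, capped = FALSE),
    data.table::data.table(site = site, condition = cond_b,
                           replicate = seq_along(b), ambiguous = FALSE,
                           log2_ratio = b, n_psms = 1L, capped = FALSE)
  ))
}

test_that("stereo_compare computes delta and Welch p against an oracle", {
  q <- stereo_quants(c(3.0, 3.2), c(0.1, -0.1))
  st <- stereo_compare(q, "Sa", "Ra")
  expect_equal(st$delta, 3.1)
  # independent Welch oracle: direct formula with pt()
  va <- var(c(3.0, 3.2)) / 2; vb <- var(c(0.1, -0.1)) / 2
  tt <- 3.1 / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / 1 + vb^2 / 1)
  p_oracle <- 2 * pt(-abs(tt), df)
  expect_equal(st$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(st$selective_for, "A")
})

test_that("stereo_compare degenerate and skip cases", {
  ident <- stereo_compare(stereo_quants(c(2, 2), c(2, 2)), "Sa", "Ra")
  expect_equal(ident$delta, 0)
  expect_equal(ident$p_value, 1)
  expect_equal(ident$selective_for, "none")
  cancel <- stereo_compare(stereo_quants(c(2, -2), c(0, 0)), "Sa", "Ra")
  expect_equal(cancel$delta, 0)
  expect_equal(cancel$selective_for, "none")
  # one-replicate side is skipped with a reason
  st <- stereo_compare(stereo_quants(3, c(0, 0)), "Sa", "Ra")
  expect_equal(nrow(st), 0L)
  expect_equal(attr(st, "skipped")[["too-few-replicates"]], 1L)
})

test_that("stereo_compare antisymmetry under A/B swap", {
  withr::local_seed(11)
  for (i in 1:25) {
    a <- rnorm(2, 2); b <- rnorm(2)
    q <- stereo_quants(a, b)
    fwd <- stereo_compare(q, "Sa", "Ra")
    rev <- stereo_compare(q, "Ra", "Sa")
    expect_equal(fwd$delta, -rev$delta)
    expect_equal(fwd$p_value, rev$p_value)
    swap <- c(A = "B", B = "A", none = "none")
    expect_equal(unname(swap[fwd$selective_for]), rev$selective_for)
  }
})

test_that("condition grammar and dose matrix", {
  pc <- parse_condition(c("BEH-1-Sa@5uM", "BEH-1-Sa@100uM", "KB2"))
  expect_equal(pc$compound, c("BEH-1-Sa", "BEH-1-Sa", "KB2"))
  expect_equal(pc$concentration, c(5, 100, NA))
  expect_error(parse_condition("BEH-1-Sa@lots"), "unparseable")

  called <- data.table::data.table(
    site = c("P1_C3", "P1_C3", "P2_C7"),
    condition = c("BEH-1-Sa@5uM", "BEH-1-Sa@100uM", "BEH-1-Sa@100uM"),
    mean_log2 = c(0.5, 3.2, 1.0),
    call = "not-liganded"
  )
  dm <- dose_response_table(called)
  expect_equal(names(dm), c("site", "BEH-1-Sa@5uM", "BEH-1-Sa@100uM"))
  # strongest |mean| first; missing cell is NA
  expect_equal(dm$site, c("P1_C3", "P2_C7"))
  expect_true(is.na(dm[site == "P2_C7"][["BEH-1-Sa@5uM"]]))
  single <- dose_response_table(called[condition == "BEH-1-Sa@100uM"])
  expect_equal(names(single), c("site", "BEH-1-Sa@100uM"))
  expect_error(dose_response_table(called[site == "none"]), "no ")
})
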