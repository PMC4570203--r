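# Hand-built universe with fully controlled clan structure.
clan_universe <- function(clans) {
  # clans: named character vector accession -> clan (NA = clanless)
  tab <- assignment_table(paste0("q", seq_along(clans)),
                          paste0("2.A.40.", seq_along(clans), ".1"))
  h <- hit_table(data.frame(seq_id = paste0("q", seq_along(clans)),
                            family = names(clans), clan = unname(clans),
                            start = 1L, end = 50L, evalue = 1e-30, bitscore = 1))
  reg <- family_registry(names(clans), names(clans), unname(clans))
  list(sf = superfamily_def("SFX", "2.A.40"), tab = tab, hits = h, registry = reg)
}

test_that("dominant clans are the mode of labeled matched families", {
  u <- clan_universe(c(PF1 = "CLA", PF2 = "CLA", PF3 = "CLA", PF4 = "CLA",
                       PF5 = "CLB"))
  corr <- superfamily_to_clans(u$sf, u$tab, u$hits, u$registry)
  expect_equal(corr$dominant_clan, "CLA")
  expect_equal(corr$dominant_fraction, 0.8)
  expect_equal(corr$outliers, "PF5")
  props <- propose_clan_changes(corr)
  expect_equal(nrow(props), 1L)
  expect_equal(props$accession, "PF5")
  expect_equal(props$proposed_clan, "CLA")
})

test_that("ties yield no dominant clan and no proposals", {
  u <- clan_universe(c(PF1 = "CLA", PF2 = "CLB"))
  corr <- superfamily_to_clans(u$sf, u$tab, u$hits, u$registry)
  expect_true(is.na(corr$dominant_clan))
  expect_length(corr$dominant_fraction, 2)
  expect_equal(nrow(propose_clan_changes(corr)), 0L)
})

test_that("clanless matched families are proposed to join a unanimous clan", {
  u <- clan_universe(c(PF1 = "CLA", PF2 = "CLA", PF3 = NA))
  corr <- superfamily_to_clans(u$sf, u$tab, u$hits, u$registry)
  expect_equal(corr$dominant_fraction, 1.0)  # fraction among labeled families
  expect_equal(corr$outliers, "PF3")
  props <- propose_clan_changes(corr)
  expect_equal(props$accession, "PF3")
  expect_true(is.na(props$current_clan))
})

test_that("the 0.6 majority threshold is inclusive and configurable", {
  # exactly 3 of 5 labeled -> 0.6: proposals fire
  u <- clan_universe(c(PF1 = "CLA", PF2 = "CLA", PF3 = "CLA", PF4 = "CLB",
                       PF5 = "CLC"))
  corr <- superfamily_to_clans(u$sf, u$tab, u$hits, u$registry)
  expect_equal(corr$dominant_fraction, 0.6)
  expect_equal(nrow(propose_clan_changes(corr)), 2L)
  # 0.5 stays silent
  u2 <- clan_universe(c(PF1 = "CLA", PF2 = "CLA", PF3 = "CLB", PF4 = "CLC"))
  corr2 <- superfamily_to_clans(u2$sf, u2$tab, u2$hits, u2$registry)
  expect_equal(corr2$dominant_fraction, 0.5)
  expect_equal(nrow(propose_clan_changes(corr2)), 0L)
  # min_fraction 0 always proposes; > 1 never does
  expect_equal(nrow(propose_clan_changes(corr2, min_fraction = 0)), 2L)
  expect_equal(nrow(propose_clan_changes(corr, min_fraction = 1.01)), 0L)
})

test_that("raising the E-value cutoff never shrinks the matched set", {
  b <- default_bundle()
  fams <- unique(b$manifest$families$tc_prefix3[
    b$manifest$families$superfamily == "SF1"])
  sf <- superfamily_def("SF1", fams)
  prev <- -1L
  for (ev in c(1e-30, 1e-25, 1e-20, 1e-10, 1)) {
    n <- nrow(superfamily_to_clans(sf, b$assignments, b$hits, b$registry,
                                   evalue_max = ev)$matched)
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("candidate verdicts implement the TMS and E-window boundaries", {
  expect_true(candidate_verdict(1, 1e-4)$pass)     # delta 1, mid-window
  expect_false(candidate_verdict(2, 1e-4)$pass)    # delta 2
  expect_equal(candidate_verdict(2, 1e-4)$fail_reason, "tms_mismatch")
  expect_true(candidate_verdict(0, 0.1)$pass)      # upper bound inclusive
  expect_true(candidate_verdict(0, 1e-7)$pass)     # lower bound inclusive
  expect_false(candidate_verdict(0, 1e-8)$pass)    # too close
  expect_equal(candidate_verdict(0, 1e-8)$fail_reason, "evalue_too_close")
  expect_false(candidate_verdict(0, 0.11)$pass)
  expect_equal(candidate_verdict(0, 0.11)$fail_reason, "evalue_too_weak")
  expect_true(candidate_verdict(-1, 1e-3)$pass)    # delta is absolute
})

test_that("candidate clans require strictly more than half the clan hitting", {
  # CLA: 2 of 4 families hit (exactly 0.5) -> excluded; CLB: 2 of 3 -> selected
  tab <- assignment_table(c("q1", "q2", "q3", "q4"),
                          c("2.A.40.1.1", "2.A.40.2.1", "2.A.40.3.1", "2.A.40.4.1"))
  h <- hit_table(data.frame(
    seq_id = c("q1", "q2", "q3", "q4"),
    family = c("PA1", "PA2", "PB1", "PB2"),
    clan = c("CLA", "CLA", "CLB", "CLB"),
    start = 1L, end = 50L, evalue = 1e-30, bitscore = 1))
  reg <- family_registry(
    c("PA1", "PA2", "PA3", "PA4", "PB1", "PB2", "PB3"),
    c("PA1", "PA2", "PA3", "PA4", "PB1", "PB2", "PB3"),
    c("CLA", "CLA", "CLA", "CLA", "CLB", "CLB", "CLB"))
  seqs <- c(q1 = strrep("MKLV", 30), q2 = strrep("MKIV", 30),
            q3 = strrep("MKLF", 30), q4 = strrep("MKVF", 30),
            rB = strrep("MELV", 30))
  tms <- list(q1 = cbind(start = 10L, end = 30L), q2 = cbind(start = 10L, end = 30L),
              q3 = cbind(start = 10L, end = 30L), q4 = cbind(start = 10L, end = 30L),
              rB = cbind(start = 10L, end = 30L))
  sf <- superfamily_def("SFX", "2.A.40")
  res <- candidate_pipeline(sf, tab, h, reg, seqs, tms,
                            family_reps = c(PB3 = "rB", PA3 = "x", PA4 = "x"))
  # only CLB families with no hits are screened: PB3
  expect_equal(res$accession, "PB3")
  expect_equal(unname(res$clan_hit_fraction), 2 / 3)
  # evidence trail is consistent with the rule
  expect_equal(res$pass,
               candidate_verdict(res$delta_tms, res$evalue)$pass)
  # a family without a representative is flagged, no verdict
  reg2 <- family_registry(c("PB1", "PB2", "PB3"), c("PB1", "PB2", "PB3"),
                          c("CLB", "CLB", "CLB"))
  res2 <- candidate_pipeline(sf, tab, h, reg2, seqs, tms,
                             family_reps = character(0))
  expect_true(is.na(res2$pass))
  expect_equal(res2$fail_reason, "no_representative")
})

test_that("pipeline verdicts on planted candidates equal the brute-force rule", {
  if (is.null(.fixture_cache$cand)) {
    .fixture_cache$cand <- generate_fixture(
      fixture_spec(seed = 303, n_candidates = 6, clan_noise = 0))
  }
  b <- .fixture_cache$cand
  fams <- unique(b$manifest$families$tc_prefix3[
    b$manifest$families$superfamily == "SF1"])
  sf <- superfamily_def("SF1", fams)
  res <- candidate_pipeline(sf, b$assignments, b$hits, b$registry, b$seqs,
                            b$tms, b$family_reps)
  expect_gt(nrow(res), 0)
  for (k in seq_len(nrow(res))) {
    v <- candidate_verdict(res$delta_tms[k], res$evalue[k])
    expect_equal(res$pass[k], v$pass)
    expect_equal(res$fail_reason[k], v$fail_reason)
  }
  # TMS deltas reflect the planted architecture changes
  cand <- b$manifest$candidates
  planted <- cand[match(res$accession, cand$accession), ]
  expect_equal(res$rep_tms, planted$n_tms)
  # invariant to the order of assigned sequences
  perm <- sample(nrow(b$assignments))
  tab2 <- b$assignments[perm, ]
  class(tab2) <- c("assignment_table", "data.frame")
  res2 <- candidate_pipeline(sf, tab2, b$hits, b$registry, b$seqs,
                             b$tms, b$family_reps)
  expect_equal(res2[order(res2$accession), ], res[order(res$accession), ],
               ignore_attr = TRUE)
})
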