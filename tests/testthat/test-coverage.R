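# Small, fast universe for backend-driven tests.
small_bundle <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- generate_fixture(
      fixture_spec(seed = 202, n_superfamilies = 2, families_per_superfamily = 2,
                   seqs_per_family = 10, orphan_fraction = 0.2))
  }
  .fixture_cache$small
}

test_that("missing-representative discovery matches the manifest oracle", {
  b <- default_bundle()
  miss <- find_missing(b$assignments, b$hits, b$seqs)
  expect_setequal(miss, oracle_missing(b))
  # every reported id is an orphan in a kept class
  expect_true(all(miss %in% b$manifest$orphan_ids))
})

test_that("class filtering hides orphans outside the kept classes", {
  tab <- assignment_table(c("o1", "o2"), c("9.A.1.1.1", "1.A.1.1.1"))
  seqs <- c(o1 = "MKLVMKLV", o2 = "MKLVMKLV")
  empty_hits <- hit_table(data.frame(seq_id = character(0), family = character(0),
                                     clan = character(0), start = integer(0),
                                     end = integer(0), evalue = numeric(0),
                                     bitscore = numeric(0)))
  expect_equal(find_missing(tab, empty_hits, seqs), "o2")
  expect_equal(find_missing(tab[tab$seq_id == "o1", ], empty_hits, seqs),
               character(0))  # orphans only in class 9 -> nothing
  # all sequences hit -> nothing
  h <- hit_table(data.frame(seq_id = "o2", family = "PF1", clan = NA,
                            start = 1L, end = 8L, evalue = 1e-10, bitscore = 1))
  expect_equal(find_missing(tab, h, seqs), character(0))
})

test_that("the built-in backend recovers planted families exactly", {
  b <- small_bundle()
  be <- pairwise_backend()
  man <- b$manifest$sequences
  for (fam in unique(man$family)) {
    q <- man$seq_id[man$family == fam][1]
    expect_setequal(be(q, b$seqs, 2), man$seq_id[man$family == fam])
  }
  expect_error(be("nope", b$seqs, 2), "not found")
})

test_that("expansion retains seeds at the >= threshold, tolerating failures", {
  b <- small_bundle()
  miss <- find_missing(b$assignments, b$hits, b$seqs)
  res <- expand_and_retain(miss, pairwise_backend(), b$seqs,
                           retain_threshold = 10, assignments = b$assignments)
  man <- b$manifest$sequences
  fam_of <- stats::setNames(man$family, man$seq_id)
  fam_size <- table(man$family)
  expect_equal(res$n_matches, as.integer(fam_size[fam_of[res$seq_id]]),
               ignore_attr = TRUE)
  expect_true(all(res$retained == (res$n_matches >= 10)))
  expect_equal(res$tc_prefix4, tc_prefix(
    b$assignments$tc[match(res$seq_id, b$assignments$seq_id)], 4))

  # strict >=: a fake backend pinning match counts at 99 and 100
  fake <- function(q, refdb, iterations) paste0("m", seq_len(if (q == "a") 99 else 100))
  r2 <- expand_and_retain(c("a", "b"), fake, c(a = "MK", b = "MK"))
  expect_equal(r2$retained, c(FALSE, TRUE))
  # threshold 0 retains every non-failed seed; failures are flagged
  failing <- function(q, refdb, iterations) {
    if (q == "a") stop("backend down") else "x"
  }
  r3 <- expand_and_retain(c("a", "b"), failing, c(a = "MK", b = "MK"),
                          retain_threshold = 0)
  expect_equal(r3$failed, c(TRUE, FALSE))
  expect_equal(r3$retained, c(FALSE, TRUE))
})

test_that("rescan augments hits and shrinks the missing list to a fixed point", {
  b <- default_bundle()
  miss1 <- find_missing(b$assignments, b$hits, b$seqs)
  # adding nothing changes nothing
  r0 <- rescan_iteration(b$assignments, b$hits, list(), b$seqs)
  expect_identical(r0$missing, miss1)
  expect_identical(nrow(r0$hits), nrow(b$hits))
  # families covering every orphan empty the missing list
  man <- b$manifest$sequences
  orphan_fams <- unique(man$family[man$orphan])
  new_fams <- stats::setNames(
    lapply(orphan_fams, function(f) man$seq_id[man$family == f]),
    paste0("NEW", seq_along(orphan_fams)))
  r1 <- rescan_iteration(b$assignments, b$hits, new_fams, b$seqs)
  expect_length(r1$missing, 0)
  expect_true(all(r1$hits$evalue[r1$hits$family %in% names(new_fams)] == 1e-30))
  # missing list is non-increasing under any augmentation
  r2 <- rescan_iteration(b$assignments, b$hits,
                         stats::setNames(new_fams[1], "NEWX"), b$seqs)
  expect_lte(length(r2$missing), length(miss1))
  expect_error(rescan_iteration(b$assignments, b$hits,
                                stats::setNames(list("S0001"), b$hits$family[1]),
                                b$seqs), "duplicate")
})

test_that("a second rescan surfaces the subunit hidden behind a shared prefix", {
  # two nonhomologous subunits of one system share the 4-level prefix;
  # only one representative appears per iteration
  tab <- assignment_table(c("subA", "subB"), c("3.A.1.1.1", "3.A.1.1.2"))
  seqs <- c(subA = strrep("MKLV", 30), subB = strrep("GSTP", 20))
  no_hits <- hit_table(data.frame(seq_id = character(0), family = character(0),
                                  clan = character(0), start = integer(0),
                                  end = integer(0), evalue = numeric(0),
                                  bitscore = numeric(0)))
  miss1 <- find_missing(tab, no_hits, seqs)
  expect_equal(miss1, "subA")  # the longer subunit represents the group
  r <- rescan_iteration(tab, no_hits, list(NEWA = "subA"), seqs)
  expect_equal(r$missing, "subB")  # picked up by the second iteration
  r2 <- rescan_iteration(tab, r$hits, list(NEWB = "subB"), seqs)
  expect_length(r2$missing, 0)
})

test_that("unknown-function families map to the TC families they touch", {
  b <- default_bundle()
  res <- match_unknown_function(b$hits, b$registry, b$assignments)
  man <- b$manifest
  # oracle: DUF-flagged families with at least one non-orphan member
  seqs_df <- man$sequences
  expected <- sort(intersect(man$duf_accessions,
                             unique(seqs_df$family[!seqs_df$orphan])))
  expect_equal(res$accession, expected)
  # each maps back to its own planted TC family prefix
  fam_prefix <- stats::setNames(man$families$tc_prefix3, man$families$accession)
  expect_equal(res$tc_families, unname(fam_prefix[res$accession]))
  expect_true(all(res$n_tc_families == 1L))
  # a DUF with no hits is excluded
  reg2 <- family_registry("PF99999", "DUF999")
  expect_equal(nrow(match_unknown_function(b$hits, reg2, b$assignments)), 0L)
})
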