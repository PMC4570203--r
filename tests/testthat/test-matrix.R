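test_that("cell fractions average hits per sequence, multiplicity included", {
  tab <- assignment_table(paste0("s", 1:4), paste0("2.A.7.", 1:4, ".1"))
  # 2 of 4 sequences have one hit each -> fraction 0.5, bin 5
  h <- hit_table(data.frame(seq_id = c("s1", "s2"), family = "PF1", clan = NA,
                            start = 1L, end = 10L, evalue = 1e-10, bitscore = 1))
  m <- build_matrix("2.A", tab, h)
  expect_equal(unname(m$fraction["2.A.7", "PF1"]), 0.5)
  expect_equal(unname(matrix_bins(m)["2.A.7", "PF1"]), 5L)
  # tandem repeats: 2 sequences x 2 hits each -> fraction 2.0, top bin
  tab2 <- assignment_table(c("t1", "t2"), c("2.A.9.1.1", "2.A.9.1.2"))
  h2 <- hit_table(data.frame(seq_id = rep(c("t1", "t2"), each = 2),
                             family = "PF2", clan = NA,
                             start = c(1L, 101L, 1L, 101L),
                             end = c(90L, 190L, 90L, 190L),
                             evalue = 1e-10, bitscore = 1))
  m2 <- build_matrix("2.A", tab2, h2)
  expect_equal(unname(m2$fraction["2.A.9", "PF2"]), 2)
  expect_equal(unname(matrix_bins(m2)["2.A.9", "PF2"]), 9L)
  expect_error(build_matrix("7.Q", tab, h), "not present")
})

test_that("the fixture matrix equals a brute-force recount", {
  b <- default_bundle()
  m <- build_matrix("1.A", b$assignments, b$hits)
  fam3 <- tc_prefix(b$assignments$tc, 3)
  for (f in m$rows) {
    ids <- unique(b$assignments$seq_id[fam3 == f])
    for (p in m$cols) {
      n_hits <- sum(b$hits$seq_id %in% ids & b$hits$family == p &
                      b$hits$evalue <= 1e-5)
      want <- if (n_hits == 0) NA_real_ else n_hits / length(ids)
      expect_equal(unname(m$fraction[f, p]), want)
    }
  }
  # rows appear even when empty: all subclass families are rows
  expect_setequal(m$rows, unique(fam3[b$assignments$cls == 1]))
})

test_that("binning follows min(floor(10f), 9) across [0, 3]", {
  f <- c(seq(0.001, 3, by = 0.013), 0.1, 0.9, 0.999, 1.0, 1.5, 2.5)
  expect_equal(bin_fraction(f), pmin(as.integer(floor(10 * f)), 9L))
  expect_equal(bin_fraction(1.0), 9L)   # "average fraction > 1" rule boundary
  expect_equal(bin_fraction(0.95), 9L)
  expect_equal(bin_fraction(0), 0L)
  expect_error(bin_fraction(-0.1), "fraction")
})

test_that("isolated cells and split patterns match the exhaustive oracle", {
  diagm <- match_matrix("2.A", paste0("r", 1:3), paste0("c", 1:3),
                        diag(3) * 0.5 + ifelse(diag(3) == 0, NA, 0))
  p <- find_patterns(diagm)
  expect_equal(nrow(p$isolated), 3L)
  expect_length(p$multi_hit_rows, 0)
  full <- match_matrix("2.A", c("r1", "r2"), c("c1", "c2"),
                       matrix(0.4, 2, 2))
  pf <- find_patterns(full)
  expect_equal(nrow(pf$isolated), 0L)
  expect_equal(pf$multi_hit_rows, c("r1", "r2"))
  expect_equal(pf$multi_hit_cols, c("c1", "c2"))
  # random sparse matrices against the brute-force scan
  set.seed(73)
  for (k in 1:50) {
    nr <- sample(3:12, 1); nc <- sample(3:12, 1)
    frac <- matrix(ifelse(runif(nr * nc) < 0.15, round(runif(nr * nc), 3), NA),
                   nr, nc)
    frac[frac %in% 0] <- 0.5
    m <- match_matrix("2.A", paste0("r", 1:nr), paste0("c", 1:nc), frac)
    got <- find_patterns(m)$isolated
    want <- brute_isolated(frac)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_setequal(paste(got$row, got$col),
                      vapply(want, function(ij) paste0("r", ij[1], " c", ij[2]), ""))
    }
  }
  # an isolated cell never sits in a multi-hit row or column
  b <- default_bundle()
  mm <- build_matrix("2.A", b$assignments, b$hits)
  pp <- find_patterns(mm)
  expect_length(intersect(pp$isolated$row, pp$multi_hit_rows), 0)
  expect_length(intersect(pp$isolated$col, pp$multi_hit_cols), 0)
})

test_that("adjacent-neighbor mode only inspects orthogonal neighbors", {
  # two cells share a row but are not adjacent: never line-isolated, both
  # adjacent-isolated
  frac <- matrix(NA_real_, 3, 3)
  frac[1, 1] <- 0.5; frac[1, 3] <- 0.5
  m <- match_matrix("2.A", paste0("r", 1:3), paste0("c", 1:3), frac)
  expect_equal(nrow(find_patterns(m, "line")$isolated), 0L)
  expect_equal(nrow(find_patterns(m, "adjacent")$isolated), 2L)
  # orthogonally touching cells are isolated under neither mode
  frac2 <- matrix(NA_real_, 3, 3)
  frac2[2, 2] <- 0.5; frac2[2, 3] <- 0.5
  m2 <- match_matrix("2.A", paste0("r", 1:3), paste0("c", 1:3), frac2)
  expect_equal(nrow(find_patterns(m2, "adjacent")$isolated), 0L)
})

test_that("SVG round-trips losslessly, including hand-deleted cells", {
  b <- default_bundle()
  m <- build_matrix("1.A", b$assignments, b$hits)
  f <- withr::local_tempfile(fileext = ".svg")
  write_svg(m, f)
  back <- read_svg(f)
  expect_identical(back$rows, m$rows)
  expect_identical(back$cols, m$cols)
  expect_identical(back$fraction, m$fraction)  # full-precision attributes
  # delete one cell element as a hand edit would
  doc <- xml2::read_xml(f)
  cells <- xml2::xml_find_all(doc, ".//*[local-name()='rect'][@data-row]")
  victim <- cells[[1]]
  vr <- xml2::xml_attr(victim, "data-row"); vc <- xml2::xml_attr(victim, "data-col")
  xml2::xml_remove(victim)
  f2 <- withr::local_tempfile(fileext = ".svg")
  xml2::write_xml(doc, f2)
  edited <- read_svg(f2)
  expect_true(is.na(edited$fraction[vr, vc]))
  edited$fraction[vr, vc] <- m$fraction[vr, vc]
  expect_identical(edited$fraction, m$fraction)  # nothing else changed
})

test_that("degenerate SVGs are rejected or handled", {
  empty <- match_matrix("9.Z", c("r1", "r2"), character(0),
                        matrix(numeric(0), nrow = 2, ncol = 0))
  f <- withr::local_tempfile(fileext = ".svg")
  write_svg(empty, f)
  back <- read_svg(f)
  expect_identical(back$rows, c("r1", "r2"))
  expect_length(back$cols, 0)
  f2 <- withr::local_tempfile(fileext = ".svg")
  writeLines("", f2)
  expect_error(read_svg(f2), "SVG")
  f3 <- withr::local_tempfile(fileext = ".svg")
  xml2::write_xml(xml2::xml_new_root("svg"), f3)
  expect_error(read_svg(f3), "data-subclass")
})

test_that("pattern reports carry SVG coordinates that locate the cells", {
  frac <- matrix(NA_real_, 2, 2); frac[2, 2] <- 0.7
  m <- match_matrix("2.A", c("r1", "r2"), c("c1", "c2"), frac)
  f <- withr::local_tempfile(fileext = ".svg")
  write_svg(m, f)
  p <- find_patterns(m)
  doc <- xml2::read_xml(f)
  rect <- xml2::xml_find_first(doc, ".//*[local-name()='rect'][@data-row]")
  expect_equal(as.numeric(xml2::xml_attr(rect, "x")), p$isolated$svg_x[1])
  expect_equal(as.numeric(xml2::xml_attr(rect, "y")), p$isolated$svg_y[1])
  f4 <- withr::local_tempfile(fileext = ".tsv")
  write_patterns(p, f4)
  rep <- utils::read.delim(f4)
  expect_equal(rep$kind[1], "isolated")
})

test_that("topology overlay counts fully contained segments per hit", {
  tab <- assignment_table("s1", "2.A.7.1.1")
  h <- hit_table(data.frame(seq_id = "s1", family = "PF1", clan = NA,
                            start = 1L, end = 200L, evalue = 1e-10, bitscore = 1))
  tms <- list(s1 = cbind(start = c(10L, 50L), end = c(30L, 70L)))
  rv <- repfam_view("2.A.7", tab, h, tms)
  expect_equal(rv$per_hit$n_tms_inside, 2L)
  # a hit covering only half a TMS does not count it
  h2 <- hit_table(data.frame(seq_id = "s1", family = "PF1", clan = NA,
                             start = 20L, end = 200L, evalue = 1e-10, bitscore = 1))
  expect_equal(repfam_view("2.A.7", tab, h2, tms)$per_hit$n_tms_inside, 1L)
  # sequences without annotation are skipped with a warning
  expect_warning(rv3 <- repfam_view("2.A.7", tab, h, list()), "without TMS")
  expect_equal(nrow(rv3$per_hit), 0L)
})

test_that("fixture families average the planted TMS count per hit", {
  b <- default_bundle()
  fam3 <- unique(tc_prefix(b$assignments$tc, 3))[1]
  rv <- repfam_view(fam3, b$assignments, b$hits, b$tms)
  expect_true(all(rv$per_family$mean_tms_per_hit ==
                    b$manifest$spec$n_tms))
})
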