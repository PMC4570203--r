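# 10-step light-to-dark red ramp used for cell shading.
.matrix_ramp <- function() grDevices::colorRampPalette(c("#FFF5F0", "#67000D"))(10)

#' Bin an average match fraction on the 10-increment shade scale
#'
#' `bin = floor(10 * fraction)` clamped to 9: fractions in `[0.9, 1)` and
#' every fraction of 1 or more (families averaging more than one hit per
#' sequence, e.g. tandem repeats) land in the top bin.
#'
#' @param fraction Numeric vector of average match fractions (>= 0).
#' @return Integer bins in 0..9.
#' @export
bin_fraction <- function(fraction) {
  stopifnot(all(fraction >= 0, na.rm = TRUE))
  pmin(as.integer(floor(10 * fraction)), 9L)
}

#' Build the TC-family x domain-family match matrix for a subclass
#'
#' For every TC family (third hierarchy level) in the chosen subclass and
#' every domain family matching any of its sequences at `evalue_max` or
#' better, the cell holds the average number of hits per sequence:
#' (total hits of the domain family over the TC family's sequences,
#' counting multiple hits per sequence) / (number of sequences in the TC
#' family). TC families with no match keep an all-empty row - an
#' unrepresented family is itself a finding; domain families appear as
#' columns only when matched somewhere.
#'
#' @param subclass Subclass label like `"2.A"` (class.subclass).
#' @param assignments An assignment table.
#' @param hits A `hit_table`.
#' @param evalue_max Inclusive E-value threshold (default 1e-5).
#' @return A `match_matrix`: list with `subclass`, `rows` (TC family
#'   prefixes), `cols` (domain family accessions), and `fraction` (numeric
#'   rows x cols matrix, `NA` for empty cells).
#' @export
build_matrix <- function(subclass, assignments, hits, evalue_max = 1e-5) {
  parts <- strsplit(subclass, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("subclass must look like '2.A'", call. = FALSE)
  rows_tab <- assignments[assignments$cls == as.integer(parts[1]) &
                            assignments$subclass == parts[2], , drop = FALSE]
  if (!nrow(rows_tab)) stop("subclass ", subclass, " not present in assignments",
                            call. = FALSE)
  fam3 <- tc_prefix(rows_tab$tc, 3L)
  row_labels <- unique(fam3)[tc_order(unique(fam3))]
  hits_ok <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  col_labels <- character(0)
  frac_by <- list()
  for (f in row_labels) {
    ids <- unique(rows_tab$seq_id[fam3 == f])
    hh <- hits_ok[hits_ok$seq_id %in% ids, , drop = FALSE]
    if (nrow(hh)) {
      counts <- table(hh$family)
      frac_by[[f]] <- stats::setNames(as.numeric(counts) / length(ids), names(counts))
      col_labels <- union(col_labels, names(counts))
    } else {
      frac_by[[f]] <- stats::setNames(numeric(0), character(0))
    }
  }
  col_labels <- sort(col_labels)
  frac <- matrix(NA_real_, length(row_labels), length(col_labels),
                 dimnames = list(row_labels, col_labels))
  for (f in row_labels) {
    v <- frac_by[[f]]
    if (length(v)) frac[f, names(v)] <- v
  }
  match_matrix(subclass, row_labels, col_labels, frac)
}

#' Construct a match matrix from its parts
#'
#' @param subclass Subclass label.
#' @param rows,cols Row (TC family) and column (domain family) labels.
#' @param fraction Numeric matrix, `NA` marking empty cells; nonempty
#'   cells must be > 0.
#' @return A `match_matrix`.
#' @export
match_matrix <- function(subclass, rows, cols, fraction) {
  fraction <- as.matrix(fraction)
  stopifnot(nrow(fraction) == length(rows), ncol(fraction) == length(cols))
  dimnames(fraction) <- list(rows, cols)
  if (any(!is.na(fraction) & fraction <= 0)) {
    stop("nonempty cells must have fraction > 0", call. = FALSE)
  }
  structure(list(subclass = subclass, rows = rows, cols = cols,
                 fraction = fraction),
            class = "match_matrix")
}

#' Bins of a match matrix
#'
#' @param m A `match_matrix`.
#' @return Integer matrix of bins (0-9), `NA` for empty cells.
#' @export
matrix_bins <- function(m) {
  b <- m$fraction
  b[] <- NA_integer_
  filled <- !is.na(m$fraction)
  b[filled] <- bin_fraction(m$fraction[filled])
  storage.mode(b) <- "integer"
  b
}

#' @export
print.match_matrix <- function(x, ...) {
  cat("<match_matrix> subclass ", x$subclass, ": ", length(x$rows), " TC families x ",
      length(x$cols), " domain families, ", sum(!is.na(x$fraction)),
      " filled cells\n", sep = "")
  invisible(x)
}

# SVG geometry shared by writer, reader and pattern report.
.svg_geom <- list(cell = 22, left = 150, top = 150, pad = 10)

.cell_xy <- function(i, j) {
  g <- .svg_geom
  c(x = g$left + (j - 1L) * g$cell, y = g$top + (i - 1L) * g$cell)
}

#' Write a match matrix to SVG
#'
#' Draws the matrix as a grid of cells shaded on a 10-step light-to-dark
#' red ramp, with row labels on the left and column labels on top. Every
#' cell rect carries machine-readable attributes (`data-row`, `data-col`,
#' `data-fraction`, `data-bin`) so the file can be hand-edited (cells
#' deleted in a vector editor) and re-analyzed; fractions are written with
#' full precision and round-trip losslessly through [read_svg()]. Row and
#' column label lists are stored on the root element, so all-empty rows
#' survive the round trip.
#'
#' @param m A `match_matrix`.
#' @param path Output path.
#' @export
write_svg <- function(m, path) {
  g <- .svg_geom
  w <- g$left + length(m$cols) * g$cell + g$pad
  h <- g$top + length(m$rows) * g$cell + g$pad
  doc <- xml2::xml_new_root("svg", xmlns = "http://www.w3.org/2000/svg",
                            width = as.character(w), height = as.character(h),
                            "data-subclass" = m$subclass,
                            "data-rows" = paste(m$rows, collapse = ";"),
                            "data-cols" = paste(m$cols, collapse = ";"))
  ramp <- .matrix_ramp()
  bins <- matrix_bins(m)
  for (i in seq_along(m$rows)) {
    xml2::xml_add_child(doc, "text", m$rows[i],
                        x = as.character(g$left - 6),
                        y = as.character(g$top + (i - 0.3) * g$cell),
                        "text-anchor" = "end", "font-size" = "11")
  }
  for (j in seq_along(m$cols)) {
    xy <- .cell_xy(1L, j)
    xml2::xml_add_child(doc, "text", m$cols[j],
                        x = as.character(xy[["x"]] + g$cell / 2),
                        y = as.character(g$top - 6),
                        transform = sprintf("rotate(-60 %s %s)",
                                            xy[["x"]] + g$cell / 2, g$top - 6),
                        "font-size" = "11")
  }
  for (i in seq_along(m$rows)) {
    for (j in seq_along(m$cols)) {
      if (is.na(m$fraction[i, j])) next
      xy <- .cell_xy(i, j)
      xml2::xml_add_child(doc, "rect",
                          x = as.character(xy[["x"]]), y = as.character(xy[["y"]]),
                          width = as.character(g$cell - 1),
                          height = as.character(g$cell - 1),
                          fill = ramp[bins[i, j] + 1L],
                          "data-row" = m$rows[i], "data-col" = m$cols[j],
                          "data-fraction" = sprintf("%.17g", m$fraction[i, j]),
                          "data-bin" = as.character(bins[i, j]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a match matrix back from SVG
#'
#' Reconstructs the matrix from the machine-readable cell attributes
#' written by [write_svg()]. Cells deleted from the file (e.g. manually,
#' to filter out irrelevant hits before re-analysis) are simply absent
#' from the result.
#'
#' @param path SVG path.
#' @return A `match_matrix`.
#' @export
read_svg <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("not a readable SVG: ", path, call. = FALSE))
  need_root <- c("data-subclass", "data-rows", "data-cols")
  att <- vapply(need_root, function(a) {
    v <- xml2::xml_attr(doc, a)
    if (is.na(v)) NA_character_ else v
  }, character(1))
  if (anyNA(att)) {
    stop("SVG lacks required root attribute(s): ",
         paste(need_root[is.na(att)], collapse = ", "), call. = FALSE)
  }
  split_labels <- function(s) {
    if (identical(s, "")) character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
  }
  rows <- split_labels(att[["data-rows"]])
  cols <- split_labels(att[["data-cols"]])
  frac <- matrix(NA_real_, length(rows), length(cols),
                 dimnames = list(rows, cols))
  cells <- xml2::xml_find_all(doc, ".//*[local-name()='rect'][@data-row]")
  for (c_ in cells) {
    need <- c("data-row", "data-col", "data-fraction")
    a <- vapply(need, function(x) xml2::xml_attr(c_, x), character(1))
    if (anyNA(a)) {
      stop("SVG cell lacks attribute(s): ", paste(need[is.na(a)], collapse = ", "),
           call. = FALSE)
    }
    frac[a[["data-row"]], a[["data-col"]]] <- as.numeric(a[["data-fraction"]])
  }
  match_matrix(att[["data-subclass"]], rows, cols, frac)
}

#' Detect isolated cells and split patterns in a match matrix
#'
#' An isolated cell is a filled cell alone in both its row and its column:
#' a candidate one-to-one correspondence between a TC family and a domain
#' family. Multi-hit rows (a TC family matched by several domain families)
#' and multi-hit columns (a domain family split across TC families) are
#' the one-to-many patterns. With `neighbors = "adjacent"` isolation only
#' requires the orthogonally adjacent cells to be empty, a looser reading
#' useful for very dense matrices.
#'
#' @param m A `match_matrix`.
#' @param neighbors `"line"` (default: whole row and column must be
#'   otherwise empty) or `"adjacent"`.
#' @return A `matrix_pattern`: list with `isolated` (data.frame `row`,
#'   `col`, `fraction`, `bin`, `svg_x`, `svg_y`), `multi_hit_rows`,
#'   `multi_hit_cols`.
#' @export
find_patterns <- function(m, neighbors = c("line", "adjacent")) {
  neighbors <- match.arg(neighbors)
  filled <- !is.na(m$fraction)
  bins <- matrix_bins(m)
  iso <- list()
  if (any(filled)) {
    row_counts <- rowSums(filled)
    col_counts <- colSums(filled)
    for (i in seq_along(m$rows)) {
      for (j in seq_along(m$cols)) {
        if (!filled[i, j]) next
        ok <- if (neighbors == "line") {
          row_counts[i] == 1L && col_counts[j] == 1L
        } else {
          !(i > 1 && filled[i - 1, j]) && !(i < nrow(filled) && filled[i + 1, j]) &&
            !(j > 1 && filled[i, j - 1]) && !(j < ncol(filled) && filled[i, j + 1])
        }
        if (ok) {
          xy <- .cell_xy(i, j)
          iso[[length(iso) + 1L]] <- data.frame(
            row = m$rows[i], col = m$cols[j], fraction = m$fraction[i, j],
            bin = bins[i, j], svg_x = xy[["x"]], svg_y = xy[["y"]],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  isolated <- if (length(iso)) do.call(rbind, iso) else
    data.frame(row = character(0), col = character(0), fraction = numeric(0),
               bin = integer(0), svg_x = numeric(0), svg_y = numeric(0),
               stringsAsFactors = FALSE)
  structure(list(
    isolated = isolated,
    multi_hit_rows = m$rows[rowSums(filled) >= 2L],
    multi_hit_cols = m$cols[colSums(filled) >= 2L]),
    class = "matrix_pattern")
}

#' @export
print.matrix_pattern <- function(x, ...) {
  cat("<matrix_pattern> ", nrow(x$isolated), " isolated cell(s), ",
      length(x$multi_hit_rows), " multi-hit row(s), ",
      length(x$multi_hit_cols), " multi-hit col(s)\n", sep = "")
  invisible(x)
}

#' Write a pattern report as TSV
#'
#' One row per finding: `kind  row  col  fraction  bin  svg_x  svg_y`.
#' SVG coordinates correspond to cell positions in the written file, so
#' findings can be located in a vector editor.
#'
#' @param p A `matrix_pattern`.
#' @param path Output path.
#' @export
write_patterns <- function(p, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("kind\trow\tcol\tfraction\tbin\tsvg_x\tsvg_y", con)
  if (nrow(p$isolated)) {
    writeLines(paste("isolated", p$isolated$row, p$isolated$col,
                     sprintf("%.6g", p$isolated$fraction), p$isolated$bin,
                     p$isolated$svg_x, p$isolated$svg_y, sep = "\t"), con)
  }
  for (r in p$multi_hit_rows) writeLines(paste("multi_hit_row", r, "", "", "", "", "",
                                               sep = "\t"), con)
  for (cc in p$multi_hit_cols) writeLines(paste("multi_hit_col", "", cc, "", "", "", "",
                                                sep = "\t"), con)
  invisible(path)
}

#' Relate domain hits to transmembrane topology for one TC family
#'
#' For every (sequence, hit) of the TC family, reports the hit envelope
#' and the number of transmembrane segments falling entirely inside it
#' (a segment only partially covered by the envelope is not counted), and
#' summarizes the mean TMS-per-hit for each domain family. Sequences
#' without a TMS annotation are skipped with a warning.
#'
#' @param tc_family TC family prefix (three levels), e.g. `"2.A.7"`.
#' @param assignments An assignment table.
#' @param hits A `hit_table`.
#' @param tms Named list of segment matrices (see [read_tms()]).
#' @param evalue_max Inclusive E-value threshold (default 1e-5).
#' @return List with `per_hit` (`seq_id`, `family`, `start`, `end`,
#'   `n_tms_inside`) and `per_family` (`family`, `n_hits`,
#'   `mean_tms_per_hit`).
#' @export
repfam_view <- function(tc_family, assignments, hits, tms, evalue_max = 1e-5) {
  ids <- unique(assignments$seq_id[tc_prefix(assignments$tc, 3L) == tc_family])
  if (!length(ids)) stop("TC family ", tc_family, " not in assignments", call. = FALSE)
  no_ann <- setdiff(ids, names(tms))
  if (length(no_ann)) {
    warning("skipping ", length(no_ann), " sequence(s) without TMS annotation: ",
            paste(utils::head(no_ann, 3), collapse = ", "))
    ids <- setdiff(ids, no_ann)
  }
  hh <- hits[hits$seq_id %in% ids & hits$evalue <= evalue_max, , drop = FALSE]
  per_hit <- if (nrow(hh)) {
    data.frame(seq_id = hh$seq_id, family = hh$family, start = hh$start,
               end = hh$end,
               n_tms_inside = vapply(seq_len(nrow(hh)), function(k) {
                 tms_count(tms[[hh$seq_id[k]]], c(hh$start[k], hh$end[k]))
               }, integer(1)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(seq_id = character(0), family = character(0), start = integer(0),
               end = integer(0), n_tms_inside = integer(0), stringsAsFactors = FALSE)
  }
  per_family <- if (nrow(per_hit)) {
    agg <- stats::aggregate(n_tms_inside ~ family, per_hit, mean)
    cnt <- stats::aggregate(n_tms_inside ~ family, per_hit, length)
    data.frame(family = agg$family, n_hits = cnt$n_tms_inside,
               mean_tms_per_hit = agg$n_tms_inside, stringsAsFactors = FALSE)
  } else {
    data.frame(family = character(0), n_hits = integer(0),
               mean_tms_per_hit = numeric(0), stringsAsFactors = FALSE)
  }
  list(per_hit = per_hit, per_family = per_family)
}
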