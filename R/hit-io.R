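#' Read a domain-hit table
#'
#' The canonical dialect is TSV with header
#' `seq_id  family  clan  start  end  evalue  bitscore`, one row per match
#' of a family model to a sequence region. Coordinates are 1-based
#' inclusive. An empty `clan` field means the family is clanless.
#'
#' When `evalue_max` is given, rows with `evalue > evalue_max` are dropped
#' (the threshold is inclusive: a hit exactly at the cutoff is kept) and
#' the number of dropped rows is reported via `message()`.
#'
#' @param path Path to the TSV file.
#' @param evalue_max Optional E-value threshold; `NULL` keeps all rows.
#' @return A `hit_table`: a `data.frame` with columns `seq_id`, `family`,
#'   `clan`, `start`, `end`, `evalue`, `bitscore`.
#' @export
read_hits <- function(path, evalue_max = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (!length(lines)) stop("empty hit table: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("seq_id", "family", "clan", "start", "end", "evalue", "bitscore")
  if (length(missing_col <- setdiff(need, header))) {
    stop("hit table ", path, " is missing column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  body <- lines[-1]
  body <- body[!grepl("^#", body) & nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  parse_num <- function(i, col, integer = FALSE) {
    x <- vapply(rows, function(r) r[[match(col, header)]], character(1))
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("hit table ", path, " line ", bad[1] + 1L, ": non-numeric ", col,
           " value '", x[bad[1]], "'", call. = FALSE)
    }
    if (integer) as.integer(v) else v
  }
  get_chr <- function(col) vapply(rows, function(r) r[[match(col, header)]], character(1))
  if (length(rows)) {
    nf <- lengths(rows)
    if (any(nf < length(header))) {
      stop("hit table ", path, " line ", which(nf < length(header))[1] + 1L,
           ": expected ", length(header), " fields", call. = FALSE)
    }
    tab <- data.frame(
      seq_id = get_chr("seq_id"), family = get_chr("family"),
      clan = ifelse(get_chr("clan") == "", NA_character_, get_chr("clan")),
      start = parse_num("start", "start", integer = TRUE),
      end = parse_num("end", "end", integer = TRUE),
      evalue = parse_num("evalue", "evalue"),
      bitscore = parse_num("bitscore", "bitscore"),
      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(seq_id = character(0), family = character(0),
                      clan = character(0), start = integer(0), end = integer(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      stringsAsFactors = FALSE)
  }
  tab <- hit_table(tab)
  if (!is.null(evalue_max)) {
    kept <- tab$evalue <= evalue_max
    if (any(!kept)) message(sum(!kept), " hit(s) dropped at E-value threshold ", evalue_max)
    tab <- tab[kept, , drop = FALSE]
    rownames(tab) <- NULL
    class(tab) <- c("hit_table", "data.frame")
  }
  tab
}

#' Construct a hit table from a data.frame
#'
#' Validates coordinate and E-value invariants (`1 <= start <= end`,
#' `evalue > 0`).
#'
#' @param df A `data.frame` with columns `seq_id`, `family`, `clan`,
#'   `start`, `end`, `evalue`, `bitscore` (missing `clan`/`bitscore`
#'   columns are filled with `NA`).
#' @return A `hit_table`.
#' @export
hit_table <- function(df) {
  if (is.null(df$clan)) df$clan <- NA_character_
  if (is.null(df$bitscore)) df$bitscore <- NA_real_
  need <- c("seq_id", "family", "clan", "start", "end", "evalue", "bitscore")
  stopifnot(all(need %in% names(df)))
  df <- df[, need, drop = FALSE]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (nrow(df)) {
    if (any(df$start < 1L | df$start > df$end)) {
      stop("invalid hit coordinates: need 1 <= start <= end", call. = FALSE)
    }
    if (any(df$evalue <= 0)) stop("E-values must be > 0", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Write a hit table to TSV
#'
#' E-values and bit scores are written in scientific notation with enough
#' significant digits (17) that reading the file back reproduces the
#' doubles exactly.
#'
#' @param hits A `hit_table`.
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# domain-hit table; coordinates 1-based inclusive", con)
  writeLines("seq_id\tfamily\tclan\tstart\tend\tevalue\tbitscore", con)
  if (nrow(hits)) {
    writeLines(paste(hits$seq_id, hits$family,
                     ifelse(is.na(hits$clan), "", hits$clan),
                     hits$start, hits$end,
                     sprintf("%.16e", hits$evalue),
                     sprintf("%.16e", hits$bitscore), sep = "\t"), con)
  }
  invisible(path)
}

#' Hits of one family on one sequence, sorted by start
#'
#' @param hits A `hit_table`.
#' @param seq_id,family Query keys; either may be `NULL` to not restrict.
#' @return The matching rows, ordered by `start`.
#' @export
hits_for <- function(hits, seq_id = NULL, family = NULL) {
  sel <- rep_len(TRUE, nrow(hits))
  if (!is.null(seq_id)) sel <- sel & hits$seq_id %in% seq_id
  if (!is.null(family)) sel <- sel & hits$family %in% family
  out <- hits[sel, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Sequences with no domain hit at all
#'
#' @param seq_ids Character vector of sequence ids.
#' @param hits A `hit_table`.
#' @return The ids with zero hits, in input order.
#' @export
unmatched_sequences <- function(seq_ids, hits) {
  seq_ids[!(seq_ids %in% unique(hits$seq_id))]
}

#' Read/write protein FASTA
#'
#' Thin wrappers over [Biostrings::readAAStringSet()] /
#' [Biostrings::writeXStringSet()]; ids are truncated at the first
#' whitespace.
#'
#' @param path FASTA path.
#' @return `read_fasta`: a named [Biostrings::AAStringSet].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname read_fasta
#' @param seqs Named [Biostrings::AAStringSet] or named character vector.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "XStringSet")) seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read/write transmembrane-segment tables
#'
#' TSV with columns `seq_id`, `start`, `end`, one row per segment,
#' 1-based inclusive coordinates.
#'
#' @param path TSV path.
#' @return `read_tms`: a named list of two-column `start`/`end` matrices,
#'   one per sequence id, segments sorted by start.
#' @export
read_tms <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, comment.char = "#")
  need <- c("seq_id", "start", "end")
  if (!all(need %in% names(raw))) {
    stop("TMS table ", path, " must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  tms_from_frame(raw)
}

#' @rdname read_tms
#' @param tms Named list of segment matrices, as returned by `read_tms`.
#' @export
write_tms <- function(tms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("seq_id\tstart\tend", con)
  for (id in names(tms)) {
    seg <- tms[[id]]
    if (nrow(seg)) {
      writeLines(paste(id, seg[, "start"], seg[, "end"], sep = "\t"), con)
    }
  }
  invisible(path)
}

# Build the named-list TMS representation from a long data.frame.
tms_from_frame <- function(df) {
  sp <- split(df[, c("start", "end")], df$seq_id)
  lapply(sp, function(d) {
    m <- as.matrix(d[order(d$start), , drop = FALSE])
    dimnames(m) <- list(NULL, c("start", "end"))
    storage.mode(m) <- "integer"
    m
  })
}
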