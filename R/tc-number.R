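#' Parse a TC number
#'
#' A TC number identifies a transport system within a five-level hierarchy:
#' class (1-9), subclass (an uppercase letter), family, subfamily and
#' transport system. The fifth level may be absent, giving the four-level
#' "prefix form" that identifies a subfamily rather than a single system.
#'
#' @param text A single string such as `"2.A.7.27.1"` (full form) or
#'   `"2.A.7.27"` (prefix form).
#' @return An object of class `tc_number` with fields `cls`, `subclass`,
#'   `family`, `subfamily` and `system` (`NA` when absent).
#' @examples
#' parse_tc("2.A.7.27")
#' parse_tc("1.A.1.2.3")
#' @export
parse_tc <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  tok <- strsplit(text, ".", fixed = TRUE)[[1]]
  if (!(length(tok) %in% c(4L, 5L))) {
    stop("malformed TC number '", text, "': expected 4 or 5 dot-separated tokens, got ",
         length(tok), call. = FALSE)
  }
  cls <- .tc_int(tok[1], "class", text)
  if (cls < 1L || cls > 9L) {
    stop("malformed TC number '", text, "': class token '", tok[1],
         "' must be an integer in 1-9", call. = FALSE)
  }
  if (!grepl("^[A-Z]$", tok[2])) {
    stop("malformed TC number '", text, "': subclass token '", tok[2],
         "' must be a single uppercase letter", call. = FALSE)
  }
  out <- structure(
    list(cls = cls, subclass = tok[2],
         family = .tc_int(tok[3], "family", text),
         subfamily = .tc_int(tok[4], "subfamily", text),
         system = if (length(tok) == 5L) .tc_int(tok[5], "system", text) else NA_integer_),
    class = "tc_number")
  out
}

.tc_int <- function(tok, what, text) {
  if (!grepl("^[0-9]+$", tok) || as.integer(tok) < 1L) {
    stop("malformed TC number '", text, "': ", what, " token '", tok,
         "' must be a positive integer", call. = FALSE)
  }
  as.integer(tok)
}

#' @export
format.tc_number <- function(x, ...) {
  base <- paste(x$cls, x$subclass, x$family, x$subfamily, sep = ".")
  if (is.na(x$system)) base else paste(base, x$system, sep = ".")
}

#' @export
print.tc_number <- function(x, ...) {
  cat("<tc_number> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Truncate a TC number to its first k levels
#'
#' `tc_prefix(x, 4)` is the redundancy-grouping key used when one
#' representative protein is kept per subfamily-level group.
#'
#' @param x A `tc_number`, or a character vector of TC numbers.
#' @param k Number of leading levels to keep (1-5).
#' @return The truncated identifier(s) as character.
#' @export
tc_prefix <- function(x, k = 4L) {
  stopifnot(k %in% 1:5)
  if (inherits(x, "tc_number")) x <- format(x)
  vapply(strsplit(x, ".", fixed = TRUE), function(tok) {
    paste(tok[seq_len(min(k, length(tok)))], collapse = ".")
  }, character(1))
}

# Split TC strings into a component data.frame (system NA for prefix form).
# Validates every entry through parse_tc.
.tc_components <- function(tc) {
  parsed <- lapply(tc, parse_tc)
  data.frame(
    tc = vapply(parsed, format, character(1)),
    cls = vapply(parsed, `[[`, integer(1), "cls"),
    subclass = vapply(parsed, `[[`, character(1), "subclass"),
    family = vapply(parsed, `[[`, integer(1), "family"),
    subfamily = vapply(parsed, `[[`, integer(1), "subfamily"),
    system = vapply(parsed, `[[`, integer(1), "system"),
    stringsAsFactors = FALSE)
}

#' Order TC numbers lexicographically on their numeric/letter tuple
#'
#' Plain string sorting would put "2.A.10" before "2.A.9"; this orders on
#' the parsed (class, subclass, family, subfamily, system) tuple, with an
#' absent system level sorting before any present one.
#'
#' @param tc Character vector of TC numbers or prefixes (2-5 tokens).
#' @return An integer permutation, as [order()].
#' @export
tc_order <- function(tc) {
  toks <- strsplit(tc, ".", fixed = TRUE)
  lvl <- function(k, int = TRUE) {
    vapply(toks, function(t) {
      if (length(t) < k) if (int) "0" else "" else t[k]
    }, character(1))
  }
  order(as.integer(lvl(1)), lvl(2, int = FALSE), as.integer(lvl(3)),
        as.integer(lvl(4)), as.integer(lvl(5)))
}

#' Read a sequence-to-TC assignment table
#'
#' The table is TSV with two columns, `seq_id` and `tc_number`, and `#`
#' comment lines. A sequence id may appear on several rows (multi-role
#' proteins carry more than one TC number).
#'
#' @param path Path to the TSV file.
#' @return An assignment table: a `data.frame` with columns `seq_id`, `tc`,
#'   `cls`, `subclass`, `family`, `subfamily`, `system`.
#' @export
read_assignments <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           colClasses = "character", check.names = FALSE)
  need <- c("seq_id", "tc_number")
  if (!all(need %in% names(raw))) {
    stop("assignment table ", path, " must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  assignment_table(raw$seq_id, raw$tc_number)
}

#' Build an assignment table from vectors
#'
#' @param seq_id Character vector of sequence identifiers.
#' @param tc Character vector of TC numbers, parallel to `seq_id`.
#' @return An assignment table (see [read_assignments()]).
#' @export
assignment_table <- function(seq_id, tc) {
  stopifnot(length(seq_id) == length(tc))
  comp <- .tc_components(tc)
  out <- cbind(data.frame(seq_id = as.character(seq_id), stringsAsFactors = FALSE), comp)
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' Write an assignment table back to TSV
#'
#' @param table An assignment table.
#' @param path Output path.
#' @export
write_assignments <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("seq_id\ttc_number", con)
  if (nrow(table)) {
    writeLines(paste(table$seq_id, table$tc, sep = "\t"), con)
  }
  invisible(path)
}

#' Keep only assignments whose TC class is in a given set
#'
#' A sequence carrying TC numbers in both kept and dropped classes retains
#' only its kept rows. The default keeps classes 1-5 and 8, excluding
#' class 9 (systems of unknown mechanism).
#'
#' @param table An assignment table.
#' @param keep Integer vector of class indices to retain; must be nonempty.
#' @return The filtered assignment table.
#' @export
filter_by_class <- function(table, keep = c(1:5, 8L)) {
  stopifnot(inherits(table, "assignment_table"), length(keep) > 0)
  out <- table[table$cls %in% as.integer(keep), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' Choose one representative sequence per four-level TC prefix
#'
#' Groups assignment rows by their subfamily-level prefix (the first four
#' TC levels) and keeps one sequence per group: the longest sequence,
#' ties broken by the lexicographically smallest id.
#'
#' @param table An assignment table.
#' @param seqs Named sequence store: an [Biostrings::AAStringSet] or a
#'   named character vector. Every id in `table` must be present.
#' @return Character vector of representative sequence ids, one per
#'   distinct four-level prefix, in prefix order.
#' @export
dedup_representatives <- function(table, seqs) {
  stopifnot(inherits(table, "assignment_table"))
  lens <- .seq_lengths(seqs)
  missing <- setdiff(unique(table$seq_id), names(lens))
  if (length(missing)) {
    stop("no sequence for id(s): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(table)) return(character(0))
  pfx <- tc_prefix(table$tc, 4L)
  groups <- split(table$seq_id, pfx)
  groups <- groups[tc_order(names(groups))]
  reps <- vapply(groups, function(ids) {
    ids <- unique(ids)
    len <- lens[ids]
    ids <- ids[len == max(len)]
    sort(ids)[1]
  }, character(1))
  unname(reps)
}

# Lengths of a sequence store, as a named integer vector.
.seq_lengths <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) {
    stats::setNames(Biostrings::width(seqs), names(seqs))
  } else if (is.character(seqs)) {
    stats::setNames(nchar(seqs), names(seqs))
  } else {
    stop("seqs must be an AAStringSet or a named character vector", call. = FALSE)
  }
}

# Coerce a sequence store to named character.
.seq_chars <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) {
    stats::setNames(as.character(seqs), names(seqs))
  } else if (is.character(seqs)) {
    seqs
  } else {
    stop("seqs must be an AAStringSet or a named character vector", call. = FALSE)
  }
}

#' Read a family registry table
#'
#' TSV with columns `accession`, `name`, `clan`, `duf_flag`; an empty clan
#' field means the family belongs to no clan. `duf_flag` is 0/1; families
#' named `DUF...` or `UPF...` are flagged as unknown-function regardless.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `accession`, `name`, `clan`
#'   (`NA` when absent) and `is_unknown_function` (logical).
#' @export
read_registry <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           colClasses = "character", check.names = FALSE)
  need <- c("accession", "name", "clan", "duf_flag")
  if (!all(need %in% names(raw))) {
    stop("family registry ", path, " must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  family_registry(raw$accession, raw$name,
                  ifelse(raw$clan == "", NA_character_, raw$clan),
                  duf_flag = raw$duf_flag == "1")
}

#' Build a family registry from vectors
#'
#' @param accession Family accessions (unique).
#' @param name Short family labels.
#' @param clan Clan accession per family, `NA` for clanless families.
#' @param duf_flag Logical: explicitly flag a family as unknown-function.
#'   Families whose name starts with `DUF` or `UPF` are always flagged.
#' @return A registry `data.frame` (see [read_registry()]).
#' @export
family_registry <- function(accession, name, clan = NA_character_, duf_flag = FALSE) {
  accession <- as.character(accession)
  if (anyDuplicated(accession)) {
    stop("duplicate accession(s) in registry: ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "), call. = FALSE)
  }
  data.frame(
    accession = accession,
    name = as.character(name),
    clan = rep_len(as.character(clan), length(accession)),
    is_unknown_function = rep_len(duf_flag, length(accession)) |
      grepl("^(DUF|UPF)", name),
    stringsAsFactors = FALSE)
}

#' Write a family registry to TSV
#'
#' @param registry A registry `data.frame`.
#' @param path Output path.
#' @export
write_registry <- function(registry, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("accession\tname\tclan\tduf_flag", con)
  if (nrow(registry)) {
    writeLines(paste(registry$accession, registry$name,
                     ifelse(is.na(registry$clan), "", registry$clan),
                     as.integer(registry$is_unknown_function), sep = "\t"), con)
  }
  invisible(path)
}
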