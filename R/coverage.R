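#' Find sequences classified in the TC system but unmatched by any domain family
#'
#' The missing-family discovery step: restrict assignments to the kept
#' classes, keep sequences with zero domain hits, and deduplicate to one
#' representative per four-level TC prefix (longest sequence, ties by
#' smallest id).
#'
#' @param assignments An assignment table.
#' @param hits A `hit_table`.
#' @param seqs Named sequence store (lengths drive representative choice).
#' @param class_filter Integer classes to keep; the default drops class 9
#'   (systems of unknown mechanism) and keeps 1-5 and 8.
#' @return Character vector of representative sequence ids.
#' @export
find_missing <- function(assignments, hits, seqs, class_filter = c(1:5, 8L)) {
  kept <- filter_by_class(assignments, class_filter)
  orphan_rows <- kept[kept$seq_id %in% unmatched_sequences(unique(kept$seq_id), hits), ,
                      drop = FALSE]
  class(orphan_rows) <- c("assignment_table", "data.frame")
  dedup_representatives(orphan_rows, seqs)
}

#' Built-in pairwise-alignment search backend
#'
#' A profile-free stand-in for an iterative profile search: a query
#' matches a reference sequence when their overlap (ends-free) alignment
#' score is at least `min_score_frac` of the smaller self-alignment score
#' (database-search semantics: tandem architectures are not penalised for
#' unaligned ends), and each
#' "iteration" re-queries with the whole match set (transitive closure
#' step). Deterministic; the query always matches itself when present in
#' the reference set. Real iterative profile-search engines can be
#' slotted in through the same contract: a function
#' `(query_id, refdb, iterations)` returning matched reference ids.
#'
#' @param params An [align_params()] list.
#' @param min_score_frac Score threshold as a fraction of the smaller
#'   self-score (default 0.4).
#' @return A backend function `(query_id, refdb, iterations)`;
#'   `refdb` is a named sequence store including the query.
#' @export
pairwise_backend <- function(params = align_params(), min_score_frac = 0.4) {
  force(params); force(min_score_frac)
  cache <- new.env(parent = emptyenv())
  function(query_id, refdb, iterations = 2L) {
    refdb <- .seq_chars(refdb)
    ids <- names(refdb)
    if (!query_id %in% ids) {
      stop("query ", query_id, " not found in reference store", call. = FALSE)
    }
    # score rows are cached per reference-store fingerprint, so repeated
    # seeds over the same store do not recompute shared rows
    fp <- paste0("db_", length(ids), "_", ids[1], "_", ids[length(ids)])
    if (is.null(cache[[fp]])) {
      cache[[fp]] <- new.env(parent = emptyenv())
      cache[[fp]]$self <- stats::setNames(
        vapply(ids, function(i) {
          .score_against(refdb[[i]], refdb[i], params, ends_free = TRUE)
        }, numeric(1)), ids)
    }
    db_cache <- cache[[fp]]
    self_score <- db_cache$self
    row_for <- function(q) {
      key <- paste0("row_", q)
      if (is.null(db_cache[[key]])) {
        db_cache[[key]] <- stats::setNames(
          .score_against(refdb[[q]], refdb, params, ends_free = TRUE), ids)
      }
      db_cache[[key]]
    }
    matched <- intersect(query_id, ids)
    frontier <- query_id
    for (it in seq_len(iterations)) {
      new_hits <- character(0)
      for (q in frontier) {
        sc <- row_for(q)
        thresh <- min_score_frac * pmin(self_score, self_score[[q]])
        new_hits <- union(new_hits, ids[sc >= thresh])
      }
      frontier <- setdiff(new_hits, matched)
      matched <- union(matched, new_hits)
      if (!length(frontier)) break
    }
    matched
  }
}

#' Expand missing-family seeds through a search backend and keep the large ones
#'
#' Each seed sequence is searched against the reference store; seeds whose
#' match set reaches `retain_threshold` (>= semantics, query included when
#' present in the reference set) are retained as worth building into a new
#' family. A backend failure on one seed flags that record and processing
#' continues.
#'
#' @param seeds Character vector of seed sequence ids.
#' @param backend A backend function, e.g. [pairwise_backend()].
#' @param refdb Named sequence store to search against.
#' @param iterations Search iterations handed to the backend (default 2).
#' @param retain_threshold Minimum match count to retain (default 100).
#' @param assignments Optional assignment table used to annotate each seed
#'   with its four-level TC prefix.
#' @return A `data.frame` with one row per seed: `seq_id`, `tc_prefix4`,
#'   `n_matches`, `retained`, `failed`.
#' @export
expand_and_retain <- function(seeds, backend, refdb, iterations = 2L,
                              retain_threshold = 100L, assignments = NULL) {
  stopifnot(iterations >= 1L)
  pfx <- rep(NA_character_, length(seeds))
  if (!is.null(assignments)) {
    m <- match(seeds, assignments$seq_id)
    pfx[!is.na(m)] <- tc_prefix(assignments$tc[m[!is.na(m)]], 4L)
  }
  out <- lapply(seq_along(seeds), function(i) {
    n <- tryCatch(length(backend(seeds[i], refdb, iterations)),
                  error = function(e) NA_integer_)
    data.frame(seq_id = seeds[i], tc_prefix4 = pfx[i],
               n_matches = n, retained = !is.na(n) && n >= retain_threshold,
               failed = is.na(n), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Re-scan after adding new families
#'
#' Emulates regenerating the model library and repeating the scan once
#' new families have been built: every member of a new family gains a
#' full-length hit to it (sentinel E-value 1e-30, far below every filter
#' in the toolkit), and the missing list is recomputed. Iterating this
#' with families built from retained seeds converges: the missing list is
#' non-increasing and reaches a fixed point.
#'
#' @param assignments An assignment table.
#' @param hits_prev The previous `hit_table`.
#' @param new_families List of `list(accession =, members =)` entries, or
#'   a named list mapping accession to member ids. Accessions must not
#'   collide with existing ones.
#' @param seqs Named sequence store (for hit coordinates and dedup).
#' @param class_filter Classes kept when recomputing the missing list.
#' @return `list(hits = augmented hit_table, missing = new missing ids)`.
#' @export
rescan_iteration <- function(assignments, hits_prev, new_families, seqs,
                             class_filter = c(1:5, 8L)) {
  if (length(new_families) && is.null(names(new_families)) &&
      !is.null(new_families[[1]]$accession)) {
    new_families <- stats::setNames(
      lapply(new_families, `[[`, "members"),
      vapply(new_families, `[[`, character(1), "accession"))
  }
  accs <- names(new_families)
  if (anyDuplicated(accs) || any(accs %in% unique(hits_prev$family))) {
    stop("duplicate family accession in rescan", call. = FALSE)
  }
  lens <- .seq_lengths(seqs)
  add <- list()
  for (acc in accs) {
    for (id in new_families[[acc]]) {
      add[[length(add) + 1L]] <- data.frame(
        seq_id = id, family = acc, clan = NA_character_,
        start = 1L, end = unname(lens[[id]]), evalue = 1e-30,
        bitscore = NA_real_, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(add)) {
    hit_table(rbind(as.data.frame(hits_prev), do.call(rbind, add)))
  } else hits_prev
  list(hits = hits,
       missing = find_missing(assignments, hits, seqs, class_filter))
}

#' Match unknown-function families to classified sequences
#'
#' Every DUF/UPF-flagged family with at least one hit to a TC-assigned
#' sequence is reported together with the distinct TC family prefixes
#' (first three levels) it touches: these are families whose function the
#' other system may already document.
#'
#' @param hits A `hit_table`.
#' @param registry A family registry.
#' @param assignments An assignment table.
#' @return A `data.frame` with `accession`, `name`, `n_tc_families`, and
#'   `tc_families` (comma-separated sorted prefixes); one row per
#'   DUF/UPF family with at least one match.
#' @export
match_unknown_function <- function(hits, registry, assignments) {
  dufs <- registry$accession[registry$is_unknown_function]
  rows <- hits[hits$family %in% dufs & hits$seq_id %in% assignments$seq_id, ,
               drop = FALSE]
  if (!nrow(rows)) {
    return(data.frame(accession = character(0), name = character(0),
                      n_tc_families = integer(0), tc_families = character(0),
                      stringsAsFactors = FALSE))
  }
  recs <- lapply(sort(unique(rows$family)), function(acc) {
    ids <- unique(rows$seq_id[rows$family == acc])
    fams <- sort(unique(tc_prefix(assignments$tc[assignments$seq_id %in% ids], 3L)))
    data.frame(accession = acc,
               name = registry$name[match(acc, registry$accession)],
               n_tc_families = length(fams),
               tc_families = paste(fams, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}
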