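#' Read superfamily definitions
#'
#' TSV with columns `superfamily_name` and `tc_prefix`, one row per member
#' TC family prefix.
#'
#' @param path TSV path.
#' @return Named list: superfamily name -> character vector of prefixes.
#' @export
read_superfamilies <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           colClasses = "character")
  need <- c("superfamily_name", "tc_prefix")
  if (!all(need %in% names(raw))) {
    stop("superfamily table ", path, " must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  split(raw$tc_prefix, raw$superfamily_name)
}

#' Superfamily definition
#'
#' @param name Superfamily name.
#' @param members Nonempty character vector of TC family prefixes
#'   (level 3, e.g. `"2.A.7"`).
#' @return A `superfamily_def`.
#' @export
superfamily_def <- function(name, members) {
  stopifnot(length(members) > 0)
  lapply(members, function(p) {
    tok <- strsplit(p, ".", fixed = TRUE)[[1]]
    if (length(tok) < 2L) stop("malformed TC prefix '", p, "'", call. = FALSE)
  })
  structure(list(name = name, members = members), class = "superfamily_def")
}

# Sequence ids assigned to any member prefix of a superfamily.
.sf_seq_ids <- function(sf, assignments) {
  sel <- rep(FALSE, nrow(assignments))
  for (p in sf$members) {
    k <- length(strsplit(p, ".", fixed = TRUE)[[1]])
    sel <- sel | tc_prefix(assignments$tc, k) == p
  }
  unique(assignments$seq_id[sel])
}

#' Map a TC superfamily to its dominant clan
#'
#' Finds every domain family matching (at `evalue_max` or better, per
#' hit) any sequence of any member TC family, looks up their clans in the
#' registry, and identifies the dominant clan as the most frequent label
#' among the clan-labeled matched families. Ties yield no dominant clan
#' (each mode's fraction is reported). Matched families outside the
#' dominant clan - including clanless ones - are the outliers. When no
#' matched family carries a clan label the correspondence is
#' unclassifiable.
#'
#' @param sf A `superfamily_def`.
#' @param assignments An assignment table.
#' @param hits A `hit_table`.
#' @param registry A family registry.
#' @param evalue_max Inclusive per-hit E-value cutoff (default 1e-25).
#' @return A `clan_correspondence`: list with `superfamily`, `matched`
#'   (data.frame `accession`, `clan`), `dominant_clan` (`NA` on tie or
#'   when unclassifiable), `dominant_fraction` (share of labeled matched
#'   families in the dominant clan; named vector of the tied modes on a
#'   tie), and `outliers`.
#' @export
superfamily_to_clans <- function(sf, assignments, hits, registry,
                                 evalue_max = 1e-25) {
  stopifnot(inherits(sf, "superfamily_def"))
  ids <- .sf_seq_ids(sf, assignments)
  hh <- hits[hits$seq_id %in% ids & hits$evalue <= evalue_max, , drop = FALSE]
  fams <- sort(unique(hh$family))
  clans <- registry$clan[match(fams, registry$accession)]
  matched <- data.frame(accession = fams, clan = clans, stringsAsFactors = FALSE)
  labeled <- matched$clan[!is.na(matched$clan)]
  if (!length(labeled)) {
    dominant <- NA_character_
    fraction <- NA_real_
    outliers <- matched$accession
  } else {
    tab <- sort(table(labeled), decreasing = TRUE)
    modes <- names(tab)[tab == tab[1]]
    if (length(modes) == 1L) {
      dominant <- modes
      fraction <- unname(tab[1]) / length(labeled)
      outliers <- matched$accession[is.na(matched$clan) | matched$clan != dominant]
    } else {
      dominant <- NA_character_
      fraction <- stats::setNames(rep(unname(tab[1]) / length(labeled),
                                      length(modes)), modes)
      outliers <- character(0)
    }
  }
  structure(list(superfamily = sf$name, matched = matched,
                 dominant_clan = dominant, dominant_fraction = fraction,
                 outliers = outliers),
            class = "clan_correspondence")
}

#' @export
print.clan_correspondence <- function(x, ...) {
  cat("<clan_correspondence> ", x$superfamily, ": ", nrow(x$matched),
      " matched families; dominant clan ",
      if (is.na(x$dominant_clan)) "none" else x$dominant_clan,
      " (fraction ", paste(round(x$dominant_fraction, 3), collapse = "/"),
      "), ", length(x$outliers), " outlier(s)\n", sep = "")
  invisible(x)
}

#' Propose clan membership changes from a correspondence
#'
#' When the dominant fraction reaches `min_fraction` (default 0.6,
#' inclusive), each outlier family - matched by the superfamily but not in
#' its dominant clan, or in no clan at all - yields one proposal to
#' consider moving it into (or joining it to) the dominant clan. Below the
#' threshold, or on a dominant-clan tie, nothing is proposed.
#'
#' @param corr A `clan_correspondence`.
#' @param min_fraction Majority threshold (default 0.6).
#' @return A `data.frame` with `superfamily`, `accession`, `current_clan`,
#'   `proposed_clan`, `dominant_fraction`.
#' @export
propose_clan_changes <- function(corr, min_fraction = 0.6) {
  stopifnot(inherits(corr, "clan_correspondence"))
  none <- data.frame(superfamily = character(0), accession = character(0),
                     current_clan = character(0), proposed_clan = character(0),
                     dominant_fraction = numeric(0), stringsAsFactors = FALSE)
  if (is.na(corr$dominant_clan) || length(corr$dominant_fraction) != 1L ||
      corr$dominant_fraction < min_fraction || !length(corr$outliers)) {
    return(none)
  }
  cur <- corr$matched$clan[match(corr$outliers, corr$matched$accession)]
  data.frame(superfamily = corr$superfamily, accession = corr$outliers,
             current_clan = cur, proposed_clan = corr$dominant_clan,
             dominant_fraction = unname(corr$dominant_fraction),
             stringsAsFactors = FALSE)
}

#' Single candidate verdict under the TMS and E-value window filters
#'
#' A candidate passes when its TMS count is the same as (or within
#' `tms_delta_max` of) its closest match's, and the alignment E-value
#' falls in `[e_min, e_max]`, both ends inclusive. The lower E-value bound
#' deliberately excludes near-identical matches: the screen targets
#' distant relatives representing genuinely new subfamilies, not proteins
#' effectively already in the system.
#'
#' @param delta_tms Absolute TMS-count difference.
#' @param evalue Alignment E-value of the best match.
#' @param tms_delta_max Maximum allowed difference (default 1).
#' @param e_min,e_max E-value window (defaults 1e-7 and 0.1, inclusive).
#' @return List with `pass` and `fail_reason` (`NA` when passing).
#' @export
candidate_verdict <- function(delta_tms, evalue, tms_delta_max = 1L,
                              e_min = 1e-7, e_max = 0.1) {
  if (abs(delta_tms) > tms_delta_max) {
    return(list(pass = FALSE, fail_reason = "tms_mismatch"))
  }
  if (evalue > e_max) return(list(pass = FALSE, fail_reason = "evalue_too_weak"))
  if (evalue < e_min) return(list(pass = FALSE, fail_reason = "evalue_too_close"))
  list(pass = TRUE, fail_reason = NA_character_)
}

# Karlin-Altschul-style conversion of a raw alignment score to an
# E-value against a database of total length db_len. Gapped BLOSUM62
# defaults; scores below the regime where the conversion is meaningful
# are clamped to bit 0 (E ~ search space size).
.score_to_evalue <- function(score, query_len, db_len,
                             lambda = 0.267, K = 0.041) {
  bit <- pmax((lambda * score - log(K)) / log(2), 0)
  query_len * db_len * 2^(-bit)
}

#' Screen clan families as candidates for entry into the TC system
#'
#' The candidate pipeline: (1) select clans in which strictly more than
#' half of the clan's registered families hit the superfamily's
#' sequences; (2) within those clans, take the families that hit no
#' TC-assigned sequence at all; (3) align each such family's
#' representative sequence against every assigned sequence and keep the
#' best match (highest score; ties broken by smaller E-value, then
#' lexicographically smaller id); (4) apply the TMS +/-1 and E-value
#' window filters via [candidate_verdict()]. Every record carries its
#' full evidence trail. E-values come from a Karlin-Altschul-style
#' conversion of the alignment bit score against the assigned-sequence
#' database size.
#'
#' @param sf A `superfamily_def`.
#' @param assignments An assignment table.
#' @param hits A `hit_table`.
#' @param registry A family registry.
#' @param seqs Named sequence store covering assigned sequences and
#'   candidate representatives.
#' @param tms Named list of TMS segment matrices; representatives without
#'   an entry fall back to [predict_tms()].
#' @param family_reps Named character: family accession -> representative
#'   sequence id. Families without one are flagged, no verdict.
#' @param params Alignment parameters.
#' @param tms_delta_max,e_min,e_max Filter settings (see
#'   [candidate_verdict()]).
#' @param exclude_prefixes Optional TC prefixes whose sequences are
#'   dropped from the comparison (e.g. multi-component systems).
#' @return A `data.frame`, one row per candidate family: `accession`,
#'   `clan`, `clan_hit_fraction`, `rep_seq`, `rep_tms`, `best_match`,
#'   `best_match_tms`, `delta_tms`, `score`, `evalue`, `pass`,
#'   `fail_reason`.
#' @export
candidate_pipeline <- function(sf, assignments, hits, registry, seqs, tms,
                               family_reps, params = align_params(),
                               tms_delta_max = 1L, e_min = 1e-7, e_max = 0.1,
                               exclude_prefixes = NULL) {
  stopifnot(inherits(sf, "superfamily_def"))
  if (!is.null(exclude_prefixes)) {
    for (p in exclude_prefixes) {
      k <- length(strsplit(p, ".", fixed = TRUE)[[1]])
      assignments <- assignments[tc_prefix(assignments$tc, k) != p, , drop = FALSE]
      class(assignments) <- c("assignment_table", "data.frame")
    }
  }
  sf_ids <- .sf_seq_ids(sf, assignments)
  sf_fams <- unique(hits$family[hits$seq_id %in% sf_ids])
  empty <- data.frame(accession = character(0), clan = character(0),
                      clan_hit_fraction = numeric(0), rep_seq = character(0),
                      rep_tms = integer(0), best_match = character(0),
                      best_match_tms = integer(0), delta_tms = integer(0),
                      score = numeric(0), evalue = numeric(0), pass = logical(0),
                      fail_reason = character(0), stringsAsFactors = FALSE)

  # step 1: clans with > 1/2 of their registered families hitting the superfamily
  clans <- unique(registry$clan[!is.na(registry$clan)])
  selected <- character(0); hit_frac <- numeric(0)
  for (cl in clans) {
    members <- registry$accession[!is.na(registry$clan) & registry$clan == cl]
    frac <- mean(members %in% sf_fams)
    if (frac > 0.5) {
      selected <- c(selected, cl)
      hit_frac <- c(hit_frac, frac)
    }
  }
  if (!length(selected)) return(empty)
  names(hit_frac) <- selected

  # step 2: families of those clans hitting no assigned sequence at all
  assigned_ids <- unique(assignments$seq_id)
  hit_fams_any <- unique(hits$family[hits$seq_id %in% assigned_ids])
  cand <- registry[!is.na(registry$clan) & registry$clan %in% selected &
                     !(registry$accession %in% hit_fams_any), , drop = FALSE]
  if (!nrow(cand)) return(empty)

  store <- .seq_chars(seqs)
  db_ids <- sort(intersect(assigned_ids, names(store)))
  db_len <- sum(nchar(store[db_ids]))
  out <- list()
  for (k in seq_len(nrow(cand))) {
    acc <- cand$accession[k]
    rep_id <- if (acc %in% names(family_reps)) family_reps[[acc]] else NA_character_
    row <- data.frame(accession = acc, clan = cand$clan[k],
                      clan_hit_fraction = unname(hit_frac[cand$clan[k]]),
                      rep_seq = rep_id, rep_tms = NA_integer_,
                      best_match = NA_character_, best_match_tms = NA_integer_,
                      delta_tms = NA_integer_, score = NA_real_, evalue = NA_real_,
                      pass = NA, fail_reason = "no_representative",
                      stringsAsFactors = FALSE)
    if (is.na(rep_id) || is.null(store[[rep_id]])) {
      out[[k]] <- row
      next
    }
    # step 3: best match among assigned sequences
    sc <- .score_against(store[[rep_id]], store[db_ids], params)
    ev <- .score_to_evalue(sc, nchar(store[[rep_id]]), db_len)
    ord <- order(-sc, ev, db_ids)
    best <- ord[1]
    # step 4: topology and E-value window
    rep_tms_n <- if (rep_id %in% names(tms)) tms_count(tms[[rep_id]]) else
      tms_count(predict_tms(store[[rep_id]]))
    match_id <- db_ids[best]
    match_tms_n <- if (match_id %in% names(tms)) tms_count(tms[[match_id]]) else
      tms_count(predict_tms(store[[match_id]]))
    verdict <- candidate_verdict(rep_tms_n - match_tms_n, ev[best],
                                 tms_delta_max, e_min, e_max)
    row$rep_tms <- rep_tms_n
    row$best_match <- match_id
    row$best_match_tms <- match_tms_n
    row$delta_tms <- rep_tms_n - match_tms_n
    row$score <- sc[best]
    row$evalue <- ev[best]
    row$pass <- verdict$pass
    row$fail_reason <- verdict$fail_reason
    out[[k]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
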