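# Cached scoring matrix: BLOSUM62 with the X row/column zeroed, so that
# ambiguity codes (all remapped to X) score 0 against everything.
.tccross_env <- new.env(parent = emptyenv())

.scoring_matrix <- function(name = "BLOSUM62") {
  key <- paste0("mat_", name)
  if (is.null(.tccross_env[[key]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    m <- e[[name]]
    m["X", ] <- 0
    m[, "X"] <- 0
    .tccross_env[[key]] <- m
  }
  .tccross_env[[key]]
}

#' Alignment parameters
#'
#' Defaults: BLOSUM62 substitution scores with affine gaps costing
#' `gap_open + L * gap_extend` for a gap of length `L` (open 8, extend 2),
#' global (end-gap-penalised) alignment. Ambiguity codes are remapped to
#' `X`, which scores 0 against every residue.
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM50"`), or a numeric matrix.
#' @param gap_open,gap_extend Positive gap penalties.
#' @return A list of class `align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 8, gap_extend = 2) {
  stopifnot(gap_open >= 0, gap_extend > 0)
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

.params_matrix <- function(params) {
  if (is.matrix(params$matrix)) params$matrix else .scoring_matrix(params$matrix)
}

# Remap anything outside the 20 standard residues to X.
.clean_seq <- function(seq) {
  seq <- toupper(as.character(seq))
  gsub("[^ARNDCQEGHILKMFPSTWYV]", "X", seq)
}

# Encode a cleaned sequence as 0-based row indices of the scoring matrix.
.encode_seq <- function(seq, mat) {
  idx <- match(strsplit(seq, "")[[1]], rownames(mat))
  idx[is.na(idx)] <- match("X", rownames(mat))
  as.integer(idx - 1L)
}

# Batch score-only global alignment of one query against many sequences.
.score_against <- function(query, others, params, ends_free = FALSE) {
  mat <- .params_matrix(params)
  qa <- .encode_seq(.clean_seq(query), mat)
  bs <- lapply(others, function(s) .encode_seq(.clean_seq(s), mat))
  .gotoh_score_multi(qa, bs, mat, params$gap_open, params$gap_extend, ends_free)
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch-style global alignment with affine gap penalties,
#' computed by a compiled Gotoh three-state recursion with a fixed
#' traceback tie preference (diagonal, then up, then left), so the same
#' pair always yields the same alignment. The result records, for every
#' alignment column, which residue of each sequence occupies it (`NA`
#' for a gap), which is what the topology-overlap bookkeeping consumes.
#'
#' @param a,b Protein sequences (character or `AAString`); nonempty.
#' @param params An [align_params()] list.
#' @return An object of class `pairwise_alignment`: list with `score`,
#'   `aligned_a`, `aligned_b` (gapped strings), `pos_a`, `pos_b`
#'   (per-column residue indices, `NA` at gaps), and `aligned_length`
#'   (residue-residue columns, gaps excluded).
#' @export
align_pair <- function(a, b, params = align_params()) {
  a <- .clean_seq(a); b <- .clean_seq(b)
  if (!nchar(a) || !nchar(b)) stop("empty sequence", call. = FALSE)
  mat <- .params_matrix(params)
  res <- .gotoh_align(.encode_seq(a, mat), .encode_seq(b, mat), mat,
                      params$gap_open, params$gap_extend)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  pos_a <- ifelse(res$pos_a == 0L, NA_integer_, res$pos_a)
  pos_b <- ifelse(res$pos_b == 0L, NA_integer_, res$pos_b)
  structure(list(
    score = res$score,
    aligned_a = paste(ifelse(is.na(pos_a), "-", ca[pos_a]), collapse = ""),
    aligned_b = paste(ifelse(is.na(pos_b), "-", cb[pos_b]), collapse = ""),
    pos_a = as.integer(pos_a), pos_b = as.integer(pos_b),
    aligned_length = sum(!is.na(pos_a) & !is.na(pos_b))),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score=", x$score,
      " columns=", length(x$pos_a),
      " aligned residues=", x$aligned_length, "\n", sep = "")
  invisible(x)
}

#' Count aligned transmembrane-segment pairs
#'
#' A segment of `a` and a segment of `b` form an aligned pair when the
#' alignment columns in which both residues lie inside the respective
#' segments cover at least `min_overlap_frac` of the shorter segment.
#' Each segment is used at most once; pairing is greedy left-to-right.
#'
#' @param alignment A `pairwise_alignment` from [align_pair()].
#' @param tms_a,tms_b Segment lists for the two sequences: a
#'   `tms_annotation` or a two-column `start`/`end` matrix, segments
#'   sorted and non-overlapping.
#' @param min_overlap_frac Fraction of the shorter segment that must be
#'   jointly aligned (default 0.5).
#' @return Integer: number of aligned segment pairs.
#' @export
map_tms_pairs <- function(alignment, tms_a, tms_b, min_overlap_frac = 0.5) {
  seg_a <- if (inherits(tms_a, "tms_annotation")) tms_a$segments else as.matrix(tms_a)
  seg_b <- if (inherits(tms_b, "tms_annotation")) tms_b$segments else as.matrix(tms_b)
  if (!nrow(seg_a) || !nrow(seg_b)) return(0L)
  pa <- alignment$pos_a; pb <- alignment$pos_b
  used_b <- rep(FALSE, nrow(seg_b))
  pairs <- 0L
  for (i in seq_len(nrow(seg_a))) {
    in_a <- !is.na(pa) & pa >= seg_a[i, 1] & pa <= seg_a[i, 2]
    len_a <- seg_a[i, 2] - seg_a[i, 1] + 1L
    for (j in seq_len(nrow(seg_b))) {
      if (used_b[j]) next
      in_b <- !is.na(pb) & pb >= seg_b[j, 1] & pb <= seg_b[j, 2]
      len_b <- seg_b[j, 2] - seg_b[j, 1] + 1L
      if (sum(in_a & in_b) >= min_overlap_frac * min(len_a, len_b)) {
        used_b[j] <- TRUE
        pairs <- pairs + 1L
        break
      }
    }
  }
  pairs
}

#' Assemble a homology verdict from its measurements
#'
#' Applies the homology significance criteria: the alignment score must
#' exceed the shuffled-null mean by strictly more than `z_cutoff`
#' standard deviations, the alignment must contain at least `min_len`
#' aligned residue pairs, and at least `min_tms_pairs` transmembrane
#' segments must align at equivalent positions. All three must hold for
#' `pass_all`.
#'
#' @param raw_score Alignment score of the real pair.
#' @param null_mean,null_sd Mean and standard deviation of the shuffled
#'   null score distribution.
#' @param aligned_length Aligned residue pairs (gaps excluded).
#' @param tms_pairs Aligned transmembrane-segment pairs.
#' @param n_shuffles Number of shuffles behind the null.
#' @param seed RNG seed used for the shuffles.
#' @param z_cutoff Strict cutoff in standard deviations (default 14: a
#'   score of exactly 14 SD, or the classic borderline 13.7, fails).
#' @param min_len Minimum aligned residue pairs (default 60, inclusive).
#' @param min_tms_pairs Minimum aligned TMS pairs (default 2, inclusive).
#' @return A `homology_verdict` list with the measurements, `z`, the
#'   individual `pass_z`/`pass_len`/`pass_tms` flags, `pass_all`, and
#'   `indeterminate` (true when `null_sd` is 0, e.g. homopolymers).
#' @export
homology_verdict <- function(raw_score, null_mean, null_sd, aligned_length,
                             tms_pairs, n_shuffles = NA_integer_,
                             seed = NA_integer_, z_cutoff = 14,
                             min_len = 60L, min_tms_pairs = 2L) {
  indeterminate <- !is.na(null_sd) && null_sd == 0
  z <- if (indeterminate) NA_real_ else (raw_score - null_mean) / null_sd
  pass_z <- if (indeterminate) NA else z > z_cutoff
  pass_len <- aligned_length >= min_len
  pass_tms <- tms_pairs >= min_tms_pairs
  structure(list(
    raw_score = raw_score, null_mean = null_mean, null_sd = null_sd, z = z,
    aligned_length = as.integer(aligned_length), tms_pairs = as.integer(tms_pairs),
    pass_z = pass_z, pass_len = pass_len, pass_tms = pass_tms,
    pass_all = isTRUE(pass_z) && pass_len && pass_tms,
    indeterminate = indeterminate,
    n_shuffles = as.integer(n_shuffles), seed = as.integer(seed),
    z_cutoff = z_cutoff, min_len = as.integer(min_len),
    min_tms_pairs = as.integer(min_tms_pairs)),
    class = "homology_verdict")
}

#' @export
print.homology_verdict <- function(x, ...) {
  cat("<homology_verdict>\n",
      "  score ", format(x$raw_score), "  null ", format(round(x$null_mean, 2)),
      " +/- ", format(round(x$null_sd, 2)), "  z = ",
      if (is.na(x$z)) "NA (indeterminate)" else format(round(x$z, 2)), " SD\n",
      "  aligned residues ", x$aligned_length, "  aligned TMS pairs ", x$tms_pairs, "\n",
      "  pass: z>", x$z_cutoff, " ", x$pass_z, "; len>=", x$min_len, " ",
      x$pass_len, "; tms>=", x$min_tms_pairs, " ", x$pass_tms,
      " => ", if (x$pass_all) "HOMOLOGOUS" else "not established", "\n", sep = "")
  invisible(x)
}

#' Shuffle-null homology significance test
#'
#' Aligns `a` against `b`, then against `n_shuffles` independent uniform
#' permutations of `b`'s residues, and expresses the real score as a
#' z-score in standard deviations of the shuffled-null distribution.
#' Only one sequence is shuffled, preserving the other's composition
#' structure; which one is shuffled does not matter beyond Monte-Carlo
#' error. A reportable verdict requires at least 1000 shuffles; smaller
#' counts are allowed only with `test_mode = TRUE`.
#'
#' @param a,b Protein sequences.
#' @param n_shuffles Number of shuffles (>= 1000 unless `test_mode`).
#' @param seed Integer seed; recorded in the verdict. The global RNG
#'   state is left untouched.
#' @param params An [align_params()] list.
#' @param tms_a,tms_b Optional segment lists (annotation or matrix); when
#'   both given, aligned TMS pairs are counted, otherwise reported as 0.
#' @param z_cutoff,min_len,min_tms_pairs,min_overlap_frac Criterion
#'   parameters, see [homology_verdict()] and [map_tms_pairs()].
#' @param test_mode Allow `n_shuffles < 1000`.
#' @param keep_null Keep the full null score vector in the verdict
#'   (`$null_scores`).
#' @return A `homology_verdict`.
#' @export
shuffle_z <- function(a, b, n_shuffles = 1000L, seed = 1L,
                      params = align_params(), tms_a = NULL, tms_b = NULL,
                      z_cutoff = 14, min_len = 60L, min_tms_pairs = 2L,
                      min_overlap_frac = 0.5, test_mode = FALSE,
                      keep_null = FALSE) {
  if (n_shuffles < 1000L && !test_mode) {
    stop("a reportable verdict needs at least 1000 shuffles; ",
         "use test_mode = TRUE for fewer", call. = FALSE)
  }
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1", call. = FALSE)
  a <- .clean_seq(a); b <- .clean_seq(b)
  aln <- align_pair(a, b, params)
  tms_pairs <- if (!is.null(tms_a) && !is.null(tms_b)) {
    map_tms_pairs(aln, tms_a, tms_b, min_overlap_frac)
  } else 0L
  chars_b <- strsplit(b, "")[[1]]
  shufs <- with_seed(seed, {
    vapply(seq_len(n_shuffles),
           function(i) paste(sample(chars_b), collapse = ""), character(1))
  })
  null_scores <- .score_against(a, shufs, params)
  v <- homology_verdict(
    raw_score = aln$score, null_mean = mean(null_scores),
    null_sd = stats::sd(null_scores), aligned_length = aln$aligned_length,
    tms_pairs = tms_pairs, n_shuffles = n_shuffles, seed = seed,
    z_cutoff = z_cutoff, min_len = min_len, min_tms_pairs = min_tms_pairs)
  if (keep_null) v$null_scores <- null_scores
  v
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded internals do not perturb user code.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
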