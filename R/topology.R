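# Kyte-Doolittle hydropathy scale.
.KD <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
         Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
         L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
         S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

#' Predict transmembrane segments from hydropathy
#'
#' A sliding-window predictor: mean Kyte-Doolittle hydropathy is computed
#' over a window centred at each position; maximal runs of above-threshold
#' window centres become segments. Runs separated by fewer than
#' `merge_gap` positions are merged, and segments shorter than `min_len`
#' residues are discarded. This is a deterministic stand-in for an
#' HMM-based topology predictor: downstream procedures only consume
#' segment lists, so any predictor can be slotted in, and externally
#' supplied ("given") annotations always take precedence over prediction.
#'
#' @param seq A single protein sequence (character or `AAString`).
#' @param window Window width in residues (odd; default 19).
#' @param threshold Mean-hydropathy cutoff for a window centre (default 1.6).
#' @param min_len Minimum segment length in residues (default 15).
#' @param merge_gap Runs separated by fewer than this many positions are
#'   merged (default 5).
#' @return A `tms_annotation`: list with `segments` (integer matrix with
#'   `start`/`end` columns, 1-based inclusive, sorted, non-overlapping)
#'   and `source = "predicted"`.
#' @export
predict_tms <- function(seq, window = 19L, threshold = 1.6, min_len = 15L,
                        merge_gap = 5L) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  empty <- structure(list(segments = .empty_segments(), source = "predicted"),
                     class = "tms_annotation")
  if (n < window) {
    warning("sequence shorter than window (", n, " < ", window, "); no segments")
    return(empty)
  }
  h <- .KD[strsplit(seq, "")[[1]]]
  h[is.na(h)] <- 0  # ambiguity codes contribute neutral hydropathy
  half <- (window - 1L) %/% 2L
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  centers <- which(!is.na(means) & means > threshold)
  if (!length(centers)) return(empty)
  # maximal runs of above-threshold centres, merging gaps < merge_gap
  breaks <- which(diff(centers) >= merge_gap + 1L)
  run_start <- centers[c(1L, breaks + 1L)]
  run_end <- centers[c(breaks, length(centers))]
  keep <- (run_end - run_start + 1L) >= min_len
  if (!any(keep)) return(empty)
  seg <- cbind(start = run_start[keep], end = run_end[keep])
  storage.mode(seg) <- "integer"
  structure(list(segments = seg, source = "predicted"), class = "tms_annotation")
}

.empty_segments <- function() {
  m <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  m
}

#' Wrap given segment coordinates as a TMS annotation
#'
#' @param segments Two-column `start`/`end` matrix (or data.frame),
#'   1-based inclusive.
#' @param source Provenance label, `"given"` by default.
#' @return A `tms_annotation`.
#' @export
tms_annotation <- function(segments, source = "given") {
  seg <- as.matrix(segments)
  if (!nrow(seg)) {
    seg <- .empty_segments()
  } else {
    colnames(seg) <- c("start", "end")
    storage.mode(seg) <- "integer"
    seg <- seg[order(seg[, "start"]), , drop = FALSE]
    if (any(seg[, "start"] > seg[, "end"])) stop("segment start > end", call. = FALSE)
    if (nrow(seg) > 1 && any(seg[-1, "start"] <= seg[-nrow(seg), "end"])) {
      stop("segments overlap", call. = FALSE)
    }
  }
  structure(list(segments = seg, source = source), class = "tms_annotation")
}

#' @export
print.tms_annotation <- function(x, ...) {
  cat("<tms_annotation> ", nrow(x$segments), " segment(s), source=", x$source,
      "\n", sep = "")
  invisible(x)
}

#' Count transmembrane segments, optionally within a region
#'
#' A segment is counted only if it lies fully inside the region; a region
#' boundary bisecting a segment excludes it.
#'
#' @param ann A `tms_annotation`, or a bare `start`/`end` segment matrix.
#' @param region Optional `c(start, end)` region (1-based inclusive);
#'   absent means the whole sequence.
#' @return Integer count.
#' @export
tms_count <- function(ann, region = NULL) {
  seg <- if (inherits(ann, "tms_annotation")) ann$segments else as.matrix(ann)
  if (!nrow(seg)) return(0L)
  if (is.null(region)) return(nrow(seg))
  sum(seg[, 1] >= region[1] & seg[, 2] <= region[2])
}
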