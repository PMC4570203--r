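# Residue alphabets used to plant topology. Transmembrane stretches are
# drawn from strongly hydrophobic residues and loops from mildly
# hydrophilic ones, and mutations resample from the same regional
# alphabet, so planted topology survives divergence (as real
# transmembrane segments conserve hydrophobicity under substitution).
.TM_ALPHABET <- c("L", "I", "V", "F")
.LOOP_ALPHABET <- c("G", "S", "T", "P", "N", "Q", "Y", "W", "A", "M")

#' Specification of a synthetic cross-classification universe
#'
#' Defines the planted structure the generator emits: superfamilies of
#' sequence families descended from common ancestors, with transmembrane
#' architecture, hierarchical TC-style assignments, a family registry with
#' clan labels, a consistent domain-hit table, and TMS annotations.
#'
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param n_superfamilies Number of superfamilies (each gets its own clan
#'   and its own class.subclass).
#' @param families_per_superfamily Families per superfamily.
#' @param seqs_per_family Sequences per family. A vector is recycled
#'   across families, so family sizes can be varied.
#' @param n_tms Planted transmembrane segments per domain unit.
#' @param tms_len Length of each planted segment (residues).
#' @param loop_len Range `c(min, max)` of inter-segment loop lengths.
#' @param divergence Per-site substitution probability from the family
#'   ancestor. A vector is recycled across families.
#' @param orphan_fraction Fraction of sequences that carry TC numbers but
#'   receive no domain hits (proteins unclassified in the domain system).
#' @param duf_fraction Fraction of families given DUF-style names
#'   (unknown-function flag set).
#' @param multihit_fraction Fraction of sequences built as a tandem repeat
#'   of the domain unit (two hits each, exercising fractions > 1).
#' @param clan_noise Fraction of families registered under a wrong clan.
#' @param classes TC class per superfamily (recycled).
#' @param indels Also apply indels when mutating descendants.
#' @param indel_rate Per-site indel probability when `indels` is on.
#' @param n_candidates Families planted in existing clans with a
#'   representative sequence but no hits and no TC assignment: input for
#'   the candidate-entry pipeline. Distributed round-robin over
#'   superfamily clans; planted TMS deltas vs. their nearest family cycle
#'   through 0, +1, -1, +2, -2, ...
#' @param candidate_divergence Substitution level used to derive candidate
#'   representatives from a member of the clan's first family.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_superfamilies = 3L,
                         families_per_superfamily = 5L, seqs_per_family = 20L,
                         n_tms = 4L, tms_len = 21L, loop_len = c(15L, 30L),
                         divergence = 0.15, orphan_fraction = 0.1,
                         duf_fraction = 0.2, multihit_fraction = 0.1,
                         clan_noise = 0.1, classes = c(1L, 2L, 3L),
                         indels = FALSE, indel_rate = 0.01,
                         n_candidates = 0L, candidate_divergence = 0.5) {
  spec <- list(seed = as.integer(seed), n_superfamilies = as.integer(n_superfamilies),
               families_per_superfamily = as.integer(families_per_superfamily),
               seqs_per_family = as.integer(seqs_per_family), n_tms = as.integer(n_tms),
               tms_len = as.integer(tms_len), loop_len = as.integer(loop_len),
               divergence = divergence, orphan_fraction = orphan_fraction,
               duf_fraction = duf_fraction, multihit_fraction = multihit_fraction,
               clan_noise = clan_noise, classes = as.integer(classes),
               indels = indels, indel_rate = indel_rate,
               n_candidates = as.integer(n_candidates),
               candidate_divergence = candidate_divergence)
  stopifnot(all(vapply(spec[c("divergence", "orphan_fraction", "duf_fraction",
                              "multihit_fraction", "clan_noise")],
                       function(x) all(x >= 0 & x <= 1), logical(1))),
            spec$n_superfamilies > 0, all(spec$families_per_superfamily > 0),
            all(spec$seqs_per_family > 0), spec$n_tms > 0)
  structure(spec, class = "fixture_spec")
}

# One ancestor: loops and TMS stretches; returns chars + segment matrix.
.make_ancestor <- function(n_tms, tms_len, loop_len) {
  chars <- character(0)
  seg <- matrix(integer(0), ncol = 2)
  for (k in seq_len(n_tms)) {
    loop <- sample(.LOOP_ALPHABET, sample(loop_len[1]:loop_len[2], 1), replace = TRUE)
    chars <- c(chars, loop)
    seg <- rbind(seg, c(length(chars) + 1L, length(chars) + tms_len))
    chars <- c(chars, sample(.TM_ALPHABET, tms_len, replace = TRUE))
  }
  chars <- c(chars, sample(.LOOP_ALPHABET, sample(loop_len[1]:loop_len[2], 1), replace = TRUE))
  colnames(seg) <- c("start", "end")
  storage.mode(seg) <- "integer"
  list(chars = chars, segments = seg)
}

# Mutate ancestor chars with region-aware substitutions; returns chars and
# the realized substitution fraction.
.mutate_unit <- function(chars, segments, divergence, indels = FALSE, indel_rate = 0.01) {
  n <- length(chars)
  in_tms <- rep(FALSE, n)
  for (r in seq_len(nrow(segments))) in_tms[segments[r, 1]:segments[r, 2]] <- TRUE
  hit <- stats::runif(n) < divergence
  out <- chars
  if (any(hit)) {
    out[hit & in_tms] <- sample(.TM_ALPHABET, sum(hit & in_tms), replace = TRUE)
    out[hit & !in_tms] <- sample(.LOOP_ALPHABET, sum(hit & !in_tms), replace = TRUE)
  }
  realized <- sum(out != chars) / n
  seg <- segments
  if (indels) {
    # loop-only indels so planted segments keep their identity; coordinates
    # are remapped through the cumulative offset
    ins_at <- which(!in_tms & stats::runif(n) < indel_rate / 2)
    del_at <- which(!in_tms & stats::runif(n) < indel_rate / 2)
    keep <- setdiff(seq_len(n), del_at)
    shift <- rep(0L, n)
    for (p in ins_at) shift[p:n] <- shift[p:n] + 1L
    for (p in del_at) if (p < n) shift[(p + 1):n] <- shift[(p + 1):n] - 1L
    pieces <- out
    for (p in rev(ins_at)) {
      pieces <- append(pieces, sample(.LOOP_ALPHABET, 1), after = p)
    }
    del_adj <- del_at + vapply(del_at, function(p) sum(ins_at <= p), integer(1))
    if (length(del_adj)) pieces <- pieces[-del_adj]
    seg[, 1] <- segments[, 1] + shift[segments[, 1]]
    seg[, 2] <- segments[, 2] + shift[segments[, 2]]
    out <- pieces
  }
  list(chars = out, realized = realized, segments = seg)
}

#' Generate a synthetic fixture bundle
#'
#' Emits an in-memory universe consistent with the planted structure of
#' `spec`, plus a bookkeeping manifest recording every planted fact, so
#' pipeline outputs can be checked against ground truth. Deterministic
#' given `spec$seed`; the caller's RNG state is untouched.
#'
#' Hit-table E-values are synthesized as a deterministic decreasing
#' function of each sequence's realized divergence from its ancestor,
#' `10^(-30 * (1 - d))`, so E-value filters are exercised meaningfully.
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `fixture_bundle` with elements `seqs` (named
#'   character), `assignments` (assignment table), `hits` (hit table),
#'   `registry`, `tms` (named list of segment matrices), `superfamilies`
#'   (data.frame `superfamily`/`tc_prefix`), `family_reps` (named
#'   character: candidate accession -> representative seq id) and
#'   `manifest`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, .generate_fixture_impl(spec))
}

.generate_fixture_impl <- function(spec) {
  n_fam_total <- spec$n_superfamilies * spec$families_per_superfamily
  fam_sizes <- rep_len(spec$seqs_per_family, n_fam_total)
  fam_div <- rep_len(spec$divergence, n_fam_total)
  sf_class <- rep_len(spec$classes, spec$n_superfamilies)

  seqs <- character(0); seq_ids <- character(0); tcs <- character(0)
  tms <- list()
  hit_rows <- list()
  seq_tab <- list(); fam_tab <- list()
  fam_clan_true <- character(n_fam_total); fam_clan_reg <- character(n_fam_total)
  fam_acc <- sprintf("PF%05d", seq_len(n_fam_total))
  is_duf <- rep(FALSE, n_fam_total)
  ancestors <- vector("list", n_fam_total)
  g <- 0L; sidx <- 0L
  for (s in seq_len(spec$n_superfamilies)) {
    clan <- sprintf("CL%04d", s)
    cls <- sf_class[s]
    for (f in seq_len(spec$families_per_superfamily)) {
      g <- g + 1L
      anc <- .make_ancestor(spec$n_tms, spec$tms_len, spec$loop_len)
      ancestors[[g]] <- anc
      is_duf[g] <- stats::runif(1) < spec$duf_fraction
      fam_clan_true[g] <- clan
      wrong <- stats::runif(1) < spec$clan_noise && spec$n_superfamilies > 1
      fam_clan_reg[g] <- if (wrong) {
        sprintf("CL%04d", sample(setdiff(seq_len(spec$n_superfamilies), s), 1))
      } else clan
      name <- if (is_duf[g]) sprintf("DUF%03d", 100L + g) else sprintf("FAM%03d", g)
      tc3 <- paste(cls, "A", f, sep = ".")
      members <- character(fam_sizes[g])
      for (i in seq_len(fam_sizes[g])) {
        sidx <- sidx + 1L
        id <- sprintf("S%04d", sidx)
        members[i] <- id
        multihit <- stats::runif(1) < spec$multihit_fraction
        mut1 <- .mutate_unit(anc$chars, anc$segments, fam_div[g],
                             spec$indels, spec$indel_rate)
        chars <- mut1$chars; segments <- mut1$segments
        realized <- mut1$realized
        units <- list(c(start = unname(segments[1, 1]),
                        end = unname(segments[nrow(segments), 2])))
        if (multihit) {
          linker <- sample(.LOOP_ALPHABET, 20, replace = TRUE)
          mut2 <- .mutate_unit(anc$chars, anc$segments, fam_div[g],
                               spec$indels, spec$indel_rate)
          off <- length(chars) + length(linker)
          segments <- rbind(segments, mut2$segments + off)
          units <- c(units, list(c(start = unname(mut2$segments[1, 1]) + off,
                                   end = unname(mut2$segments[nrow(mut2$segments), 2]) + off)))
          chars <- c(chars, linker, mut2$chars)
          realized <- (realized + mut2$realized) / 2
        }
        orphan <- stats::runif(1) < spec$orphan_fraction
        tc <- paste(tc3, ceiling(i / 5), ((i - 1L) %% 5L) + 1L, sep = ".")
        seqs[id] <- paste(chars, collapse = "")
        seq_ids <- c(seq_ids, id); tcs <- c(tcs, tc)
        tms[[id]] <- segments
        if (!orphan) {
          ev <- 10^(-30 * (1 - realized))
          for (u in units) {
            hit_rows[[length(hit_rows) + 1L]] <- data.frame(
              seq_id = id, family = fam_acc[g], clan = fam_clan_reg[g],
              start = u[["start"]], end = u[["end"]], evalue = ev,
              bitscore = round((u[["end"]] - u[["start"]] + 1) * (1 - realized) * 2, 1),
              stringsAsFactors = FALSE)
          }
        }
        seq_tab[[length(seq_tab) + 1L]] <- data.frame(
          seq_id = id, family = fam_acc[g], superfamily = sprintf("SF%d", s),
          tc = tc, orphan = orphan, multihit = multihit,
          divergence = realized, n_tms = nrow(segments), stringsAsFactors = FALSE)
      }
      fam_tab[[length(fam_tab) + 1L]] <- data.frame(
        accession = fam_acc[g], name = name, superfamily = sprintf("SF%d", s),
        tc_prefix3 = tc3, true_clan = clan, registry_clan = fam_clan_reg[g],
        is_duf = is_duf[g], n_members = fam_sizes[g], stringsAsFactors = FALSE)
    }
  }
  fam_df <- do.call(rbind, fam_tab)
  seq_df <- do.call(rbind, seq_tab)

  # candidate families: registered in an existing clan, one representative
  # sequence in the FASTA, no hits and no TC assignment
  cand_tab <- NULL; family_reps <- character(0)
  cand_acc <- character(0); cand_name <- character(0); cand_clan <- character(0)
  if (spec$n_candidates > 0) {
    deltas <- c(0L, 1L, -1L, 2L, -2L)
    for (k in seq_len(spec$n_candidates)) {
      s <- ((k - 1L) %% spec$n_superfamilies) + 1L
      target_g <- (s - 1L) * spec$families_per_superfamily + 1L
      delta <- deltas[((k - 1L) %/% spec$n_superfamilies) %% length(deltas) + 1L]
      anc <- ancestors[[target_g]]
      mut <- .mutate_unit(anc$chars, anc$segments, spec$candidate_divergence)
      chars <- mut$chars; segments <- mut$segments
      if (delta > 0) {
        for (d in seq_len(delta)) {
          loop <- sample(.LOOP_ALPHABET, 18, replace = TRUE)
          segments <- rbind(segments, c(length(chars) + length(loop) + 1L,
                                        length(chars) + length(loop) + spec$tms_len))
          chars <- c(chars, loop, sample(.TM_ALPHABET, spec$tms_len, replace = TRUE),
                     sample(.LOOP_ALPHABET, 10, replace = TRUE))
        }
      } else if (delta < 0) {
        for (d in seq_len(-delta)) {
          seg <- segments[nrow(segments), ]
          chars <- c(chars[seq_len(seg[["start"]] - 1L)],
                     if (seg[["end"]] < length(chars)) chars[(seg[["end"]] + 1L):length(chars)])
          segments <- segments[-nrow(segments), , drop = FALSE]
        }
      }
      storage.mode(segments) <- "integer"
      sidx <- sidx + 1L
      id <- sprintf("S%04d", sidx)
      acc <- sprintf("PF9%04d", k)
      seqs[id] <- paste(chars, collapse = "")
      tms[[id]] <- segments
      family_reps[acc] <- id
      cand_acc <- c(cand_acc, acc)
      cand_name <- c(cand_name, sprintf("CAND%03d", k))
      cand_clan <- c(cand_clan, sprintf("CL%04d", s))
      cand_tab <- rbind(cand_tab, data.frame(
        accession = acc, rep_seq = id, target_family = fam_acc[target_g],
        clan = sprintf("CL%04d", s), planted_delta_tms = delta,
        n_tms = nrow(segments), stringsAsFactors = FALSE))
    }
  }

  registry <- family_registry(
    c(fam_acc, cand_acc),
    c(fam_df$name, cand_name),
    c(fam_clan_reg, cand_clan))
  hits <- hit_table(if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(seq_id = character(0), family = character(0), clan = character(0),
               start = integer(0), end = integer(0), evalue = numeric(0),
               bitscore = numeric(0)))
  assignments <- assignment_table(seq_ids, tcs)
  superfamilies <- unique(fam_df[, c("superfamily", "tc_prefix3")])
  names(superfamilies) <- c("superfamily", "tc_prefix")
  rownames(superfamilies) <- NULL

  manifest <- list(
    spec = unclass(spec),
    sequences = seq_df,
    families = fam_df,
    candidates = cand_tab,
    orphan_ids = seq_df$seq_id[seq_df$orphan],
    duf_accessions = fam_df$accession[fam_df$is_duf],
    multihit_ids = seq_df$seq_id[seq_df$multihit])

  structure(list(seqs = seqs, assignments = assignments, hits = hits,
                 registry = registry, tms = tms, superfamilies = superfamilies,
                 family_reps = family_reps, manifest = manifest),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("<fixture_bundle> ", length(x$seqs), " sequences, ",
      nrow(x$manifest$families), " families, ", nrow(x$hits), " hits, ",
      length(x$manifest$orphan_ids), " orphans\n", sep = "")
  invisible(x)
}

#' Write a fixture bundle to a directory
#'
#' Writes `sequences.fasta`, `assignments.tsv`, `hits.tsv`,
#' `registry.tsv`, `tms.tsv`, `superfamilies.tsv`, `family_reps.tsv` and
#' `manifest.json`.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(bundle$seqs, p("sequences.fasta"))
  write_assignments(bundle$assignments, p("assignments.tsv"))
  write_hits(bundle$hits, p("hits.tsv"))
  write_registry(bundle$registry, p("registry.tsv"))
  write_tms(bundle$tms, p("tms.tsv"))
  utils::write.table(bundle$superfamilies, p("superfamilies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  reps <- data.frame(accession = names(bundle$family_reps),
                     seq_id = unname(bundle$family_reps))
  utils::write.table(reps, p("family_reps.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(bundle$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a fixture bundle back from a directory
#'
#' @param dir Directory written by [write_fixture()].
#' @return A `fixture_bundle` (sequences as named character; the manifest
#'   as plain lists/data.frames re-read from JSON).
#' @export
read_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  reps_df <- utils::read.delim(p("family_reps.tsv"), colClasses = "character")
  structure(list(
    seqs = .seq_chars(read_fasta(p("sequences.fasta"))),
    assignments = read_assignments(p("assignments.tsv")),
    hits = read_hits(p("hits.tsv")),
    registry = read_registry(p("registry.tsv")),
    tms = read_tms(p("tms.tsv")),
    superfamilies = utils::read.delim(p("superfamilies.tsv"), colClasses = "character"),
    family_reps = stats::setNames(reps_df$seq_id, reps_df$accession),
    manifest = jsonlite::read_json(p("manifest.json"), simplifyVector = TRUE)),
    class = "fixture_bundle")
}

#' Generate planted homologous or independent sequence pairs
#'
#' `homolog_pairs()` derives both members of each pair from a fresh common
#' ancestor (with the standard planted transmembrane architecture), each
#' mutated independently at `divergence` substitutions per site, so the
#' expected pairwise divergence is roughly twice that. `random_pairs()`
#' instead builds the two members from two independent ancestors: same
#' global architecture statistics, no common descent. Both return the
#' planted TMS annotations needed by the homology criterion.
#'
#' @param n Number of pairs.
#' @param divergence Per-copy substitution rate from the ancestor
#'   (default 0.15, i.e. pairwise divergence about 0.3).
#' @param n_tms Planted transmembrane segments (default 4).
#' @param tms_len,loop_len Architecture parameters as in [fixture_spec()].
#' @param seed Integer seed.
#' @return A list of `n` elements, each `list(a, b, tms_a, tms_b)`.
#' @export
homolog_pairs <- function(n, divergence = 0.15, n_tms = 4L, tms_len = 21L,
                          loop_len = c(15L, 30L), seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      anc <- .make_ancestor(n_tms, tms_len, loop_len)
      m1 <- .mutate_unit(anc$chars, anc$segments, divergence)
      m2 <- .mutate_unit(anc$chars, anc$segments, divergence)
      list(a = paste(m1$chars, collapse = ""), b = paste(m2$chars, collapse = ""),
           tms_a = m1$segments, tms_b = m2$segments)
    })
  })
}

#' @rdname homolog_pairs
#' @export
random_pairs <- function(n, n_tms = 4L, tms_len = 21L, loop_len = c(15L, 30L),
                         seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      a1 <- .make_ancestor(n_tms, tms_len, loop_len)
      a2 <- .make_ancestor(n_tms, tms_len, loop_len)
      list(a = paste(a1$chars, collapse = ""), b = paste(a2$chars, collapse = ""),
           tms_a = a1$segments, tms_b = a2$segments)
    })
  })
}
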