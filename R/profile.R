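# Desk-scale profile search: a position-specific scoring model with
# affine gaps stands in for profile HMMs.  Scores are log-odds in bits;
# thresholds are calibrated per profile from an empirical shuffle null
# rather than E-values.

# run expr under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build a profile model from a seed alignment
#'
#' Columns with more than 50% gaps are excluded from the match-state
#' set.  Per-column log-odds (bits) follow
#' \code{log2((obs + pseudocount * bg) / ((n + pseudocount) * bg))},
#' where `obs` counts a residue in the column, `n` is the column's
#' non-gap count and `bg` the background frequency.
#'
#' @param seed an [AlignmentBlock-class] with at least two rows
#' @param pseudocount positive smoothing mass (default 1)
#' @param background optional named background frequencies over the 20
#'   amino acids; defaults to the smoothed overall composition of the
#'   seed
#' @param gap_open,gap_extend positive affine gap penalties in bits
#' @return a [ProfileModel-class]
#' @export
buildProfile <- function(seed, pseudocount = 1, background = NULL,
                         gap_open = 5.5, gap_extend = 0.5) {
  if (length(alignmentRows(seed)) < 2L)
    stop("seed alignment must have at least 2 rows")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  m <- as.matrix(seed)
  gapfrac <- colMeans(m == "-")
  match_cols <- which(gapfrac <= 0.5)
  if (length(match_cols) == 0L) stop("no match columns in seed")
  if (is.null(background)) {
    res <- m[m %in% AA20]
    cnt <- table(factor(res, levels = AA20))
    background <- (as.numeric(cnt) + 1) / (sum(cnt) + 20)
    names(background) <- AA20
  }
  background <- background[AA20] / sum(background[AA20])
  scores <- matrix(0, nrow = 20, ncol = length(match_cols),
                   dimnames = list(AA20, NULL))
  for (k in seq_along(match_cols)) {
    col <- m[, match_cols[k]]
    col <- col[col %in% AA20]
    n <- length(col)
    obs <- as.numeric(table(factor(col, levels = AA20)))
    scores[, k] <- log2((obs + pseudocount * background) /
                          ((n + pseudocount) * background))
  }
  consensus <- AA20[apply(scores, 2, which.max)]
  prof <- new("ProfileModel", scores = scores, background = background,
              matchColumns = as.integer(match_cols),
              consensus = consensus,
              gapOpen = gap_open, gapExtend = gap_extend)
  seed_rows <- apply(m[, match_cols, drop = FALSE], 1, paste,
                     collapse = "")
  names(seed_rows) <- names(alignmentRows(seed))
  attr(prof, "seed_rows") <- seed_rows
  prof
}

# score matrix of profile columns (rows) vs sequence residues (cols)
profile_score_matrix <- function(profile, residues) {
  chars <- strsplit(residues, "")[[1]]
  idx <- match(chars, AA20)
  S <- matrix(0, nrow = ncol(profile@scores), ncol = length(chars))
  known <- !is.na(idx)
  S[, known] <- t(profile@scores)[, idx[known], drop = FALSE]
  S
}

#' Score a sequence against a profile
#'
#' Local (Smith-Waterman-style) or global affine-gap alignment of the
#' profile's match columns to a sequence.
#'
#' @param profile a [ProfileModel-class]
#' @param seq character scalar or AAString of residues
#' @param type "local" or "global"
#' @return list with `score` (bits), `qstart`/`qend` (profile columns),
#'   `start`/`end` (sequence positions) and the traceback `path`
#' @export
scoreSequence <- function(profile, seq, type = c("local", "global")) {
  type <- match.arg(type)
  seq <- as.character(seq)
  if (!nzchar(seq)) stop("empty sequence")
  S <- profile_score_matrix(profile, seq)
  al <- cpp_affine_align(S, profile@gapOpen, profile@gapExtend,
                         ifelse(type == "local", 0L, 1L))
  list(score = al$score, qstart = al$i1, qend = al$i2,
       start = al$j1, end = al$j2, path = al$path)
}

#' Calibrate a bit-score threshold from a shuffle null
#'
#' Scores `n` residue-shuffled sequences (drawn from `seqs` with
#' replacement) against the profile and returns mean + k * SD of the
#' null scores.
#'
#' @param profile a [ProfileModel-class]
#' @param seqs AAStringSet (or character) providing null compositions
#' @param n number of shuffles (default 200)
#' @param k SD multiplier (default 4)
#' @param seed RNG seed
#' @return bit-score threshold (numeric)
#' @export
calibrateBitThreshold <- function(profile, seqs, n = 200, k = 4,
                                  seed = 1) {
  seqs <- as.character(seqs)
  if (length(seqs) == 0L) stop("need sequences to calibrate against")
  res_idx <- lapply(strsplit(seqs, ""), function(ch) {
    i <- match(ch, AA20)
    i[is.na(i)] <- 0L
    i
  })
  with_seed(seed, {
    null_scores <- vapply(seq_len(n), function(i) {
      shuf <- sample(res_idx[[sample.int(length(res_idx), 1L)]])
      cpp_pssm_local_score(profile@scores, shuf, profile@gapOpen,
                           profile@gapExtend)
    }, numeric(1))
    mean(null_scores) + k * sd(null_scores)
  })
}

# gapped row (in profile-column space) for one local hit
hit_row <- function(profile_width, path, residues) {
  chars <- strsplit(residues, "")[[1]]
  row <- rep("-", profile_width)
  both <- path[, 1] > 0 & path[, 2] > 0
  row[path[both, 1]] <- chars[path[both, 2]]
  paste(row, collapse = "")
}

#' Iterative profile search against a sequence database
#'
#' Repeats for `iterations` rounds: align the profile locally to every
#' database sequence, admit hits at or above the bit threshold, add the
#' hit regions to the seed alignment and rebuild the profile (the
#' threshold is recalibrated for each rebuilt profile).  The hit list of
#' the final iteration is returned, sorted by score descending.
#'
#' @param profile a [ProfileModel-class] built from the seed alignment
#' @param database AAStringSet of candidate parent proteins
#' @param iterations number of search rounds (default 3)
#' @param threshold bit-score inclusion threshold; NULL (default)
#'   calibrates mean + 4 SD from 200 shuffles of the database
#' @param seed RNG seed for threshold calibration
#' @return data.frame of domain hits: parent_id, start, end (1-based
#'   inclusive on the parent), qstart, qend (profile columns), score,
#'   iteration
#' @export
iterativeSearch <- function(profile, database, iterations = 3,
                            threshold = NULL, seed = 1) {
  if (iterations < 1) stop("iterations must be >= 1")
  empty <- data.frame(parent_id = character(), start = integer(),
                      end = integer(), qstart = integer(),
                      qend = integer(), score = numeric(),
                      iteration = integer(), stringsAsFactors = FALSE)
  if (length(database) == 0L) return(empty)
  db <- as.character(database)
  ids <- names(database)
  prof <- profile
  hits <- empty
  for (it in seq_len(iterations)) {
    thr <- if (is.null(threshold))
      calibrateBitThreshold(prof, db, seed = seed + it - 1L)
    else threshold
    hits_it <- list()
    for (i in seq_along(db)) {
      # repeated local search with masking exposes every domain copy
      # on one parent (tandem pseudodimers give two separate hits)
      s <- db[[i]]
      for (pass in seq_len(8L)) {
        al <- scoreSequence(prof, s, "local")
        if (is.na(al$start) || al$score < thr) break
        hits_it[[length(hits_it) + 1L]] <- list(
          parent_id = ids[[i]], start = al$start, end = al$end,
          qstart = al$qstart, qend = al$qend, score = al$score,
          path = al$path)
        substr(s, al$start, al$end) <-
          strrep("X", al$end - al$start + 1L)
      }
    }
    hits <- if (length(hits_it)) {
      data.frame(
        parent_id = vapply(hits_it, `[[`, character(1), "parent_id"),
        start = vapply(hits_it, `[[`, integer(1), "start"),
        end = vapply(hits_it, `[[`, integer(1), "end"),
        qstart = vapply(hits_it, `[[`, integer(1), "qstart"),
        qend = vapply(hits_it, `[[`, integer(1), "qend"),
        score = vapply(hits_it, `[[`, numeric(1), "score"),
        iteration = it, stringsAsFactors = FALSE)
    } else empty
    if (it < iterations && length(hits_it)) {
      w <- profileWidth(prof)
      new_rows <- vapply(hits_it, function(h)
        hit_row(w, h$path, db[[match(h$parent_id, ids)]]), character(1))
      names(new_rows) <- sprintf("hit%d_%d", it, seq_along(new_rows))
      # hit rows live in the current profile's column space; rebuilt
      # profiles restrict again, keeping the coordinate system coherent
      aug <- alignmentBlock(c(profile_seed_rows(prof), new_rows))
      prof <- restrict_profile(
        buildProfile(aug, background = prof@background,
                     gap_open = prof@gapOpen,
                     gap_extend = prof@gapExtend))
    }
  }
  hits[order(-hits$score, hits$parent_id), , drop = FALSE]
}

# The iterative search keeps the working seed alignment attached to the
# profile so rebuilt profiles stay in a consistent column space.
profile_seed_rows <- function(profile) {
  attr(profile, "seed_rows") %||% stop("profile lacks seed rows")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# re-express a profile so its own match columns become 1..width
restrict_profile <- function(profile) {
  profile@matchColumns <- seq_len(ncol(profile@scores))
  profile
}

#' Filter hits by coverage of the best-scoring query
#'
#' A hit is complete when it covers at least `fraction` of the
#' best-scoring query's length, measured on the query profile's match
#' columns: keep iff (qend - qstart + 1) / best_query_length >=
#' fraction.
#'
#' @param hits data.frame from [iterativeSearch()]
#' @param best_query_length length of the best-scoring query in profile
#'   match columns; NULL (default) uses the span of the highest-scoring
#'   hit
#' @param fraction coverage fraction (default 0.90)
#' @return filtered hits data.frame
#' @export
completenessFilter <- function(hits, best_query_length = NULL,
                               fraction = 0.90) {
  if (nrow(hits) == 0L) return(hits)
  span <- hits$qend - hits$qstart + 1L
  if (is.null(best_query_length))
    best_query_length <- span[which.max(hits$score)]
  if (best_query_length <= 0) stop("best_query_length must be positive")
  hits[span / best_query_length >= fraction, , drop = FALSE]
}

#' Detect an alpha-crystallin domain in a protein
#'
#' Local profile search against an alphaCD profile; positive iff the
#' best local score reaches the bit threshold.  (In the source data the
#' equivalent annotation is a Pfam ArsA_HSP20 match.)
#'
#' @param seq character or AAString residues
#' @param acd_profile a [ProfileModel-class] built from an alphaCD seed
#'   alignment
#' @param threshold bit-score threshold (e.g. from
#'   [calibrateBitThreshold()])
#' @return list: has_acd (logical), start, end (parent coordinates, NA
#'   when negative), score
#' @export
detectAcd <- function(seq, acd_profile, threshold) {
  seq <- as.character(seq)
  if (!nzchar(seq)) stop("empty sequence")
  al <- scoreSequence(acd_profile, seq, "local")
  list(has_acd = !is.na(al$score) && al$score >= threshold,
       start = al$start, end = al$end, score = al$score)
}
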