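#' Built-in sliding-window disorder predictor
#'
#' Scores each residue by averaging a disorder propensity scale over a
#' centred window with mirrored edge padding, then squashes the windowed
#' propensity through a logistic centred at the scale midpoint (the mean
#' of the 20 scale values):
#' \deqn{ps_i = \mathrm{logistic}(k \times (\bar{x}_i - m))}
#' where \eqn{\bar{x}_i} is the window mean at residue \eqn{i}, \eqn{m}
#' the scale midpoint and \eqn{k} the steepness. Scores of 0.5 and above
#' call a residue disordered. The predictor is deterministic, constant on
#' homopolymers, and exactly mirror-symmetric: reversing the sequence
#' reverses the profile.
#'
#' Sequences too short to mirror-pad (length < window %/% 2 + 1) fall
#' back to the full-sequence mean propensity at every position.
#'
#' @param sequence protein sequence (single string over the canonical
#'   alphabet; `X` is scored at the scale midpoint).
#' @param scale named propensity vector over the 20 residues; defaults to
#'   the TOP-IDP scale.
#' @param window odd window width (residues); default 21 smooths the
#'   single-residue scale to region-level disorder signal.
#' @param steepness logistic steepness per propensity unit; default 8.
#' @param protein_id identifier stored in the profile.
#' @return a `disorder_profile` (scores in \[0, 1\], one per residue).
#' @examples
#' p <- predict_disorder(strrep("P", 40))  # polyproline: disordered
#' w <- predict_disorder(strrep("W", 40))  # polytryptophan: ordered
#' mean(p$scores) >= 0.5 && mean(w$scores) < 0.5
#' @export
predict_disorder <- function(sequence, scale = propensity_scale(),
                             window = 21L, steepness = 8,
                             protein_id = "seq") {
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  if (steepness <= 0) stop("steepness must be > 0")
  prop <- residue_propensities(sequence, scale)
  mid <- mean(scale)
  raw <- windowed_mean(prop, window)
  new_disorder_profile(protein_id, plogis(steepness * (raw - mid)),
                       "builtin")
}

residue_propensities <- function(sequence, scale) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  if (length(ch) == 0L) stop("empty sequence")
  prop <- unname(scale[ch])
  # masked residues (X or other non-canonical) score at the scale midpoint
  prop[is.na(prop)] <- mean(scale)
  prop
}

windowed_mean <- function(x, window) {
  n <- length(x)
  k <- window %/% 2L
  if (k == 0L) return(x)
  if (n < k + 1L) return(rep(mean(x), n))
  # mirror padding excluding the edge residue itself
  padded <- c(rev(x[2:(k + 1L)]), x, rev(x[(n - k):(n - 1L)]))
  cs <- cumsum(c(0, padded))
  (cs[(window + 1L):(length(padded) + 1L)] - cs[1:(n)]) / window
}

#' Predict the disorder profile of a point mutant
#'
#' The full-length mutated sequence is rescored from scratch (not a local
#' patch of the wild-type profile); the wild-type input is not modified.
#' With the built-in predictor only residues within half a window of the
#' mutated site can change score.
#'
#' @param sequence wild-type sequence.
#' @param position 1-based mutated position.
#' @param mut_aa mutant residue (must differ from the wild-type residue).
#' @param ... passed to [predict_disorder()].
#' @return a `disorder_profile` for the mutant sequence.
#' @export
predict_mutant <- function(sequence, position, mut_aa, ...) {
  position <- as.integer(position)
  if (position < 1L || position > nchar(sequence)) {
    stop("mutation position out of range")
  }
  wt <- substr(sequence, position, position)
  if (identical(wt, mut_aa)) {
    stop("mutant residue equals the wild-type residue")
  }
  mutated <- sequence
  substr(mutated, position, position) <- mut_aa
  predict_disorder(mutated, ...)
}

#' Order/disorder call from a disorder score
#'
#' A residue is called disordered when its score is at or above 0.5 and
#' ordered when below — the threshold convention used throughout the
#' package.
#'
#' @param ps numeric score(s) in \[0, 1\], or a `disorder_profile`.
#' @return character vector, `"disordered"` or `"ordered"`.
#' @export
call_state <- function(ps) {
  if (inherits(ps, "disorder_profile")) ps <- ps$scores
  if (any(ps < 0 | ps > 1)) stop("scores must lie in [0,1]")
  ifelse(ps >= 0.5, "disordered", "ordered")
}

#' Fraction of residues called disordered
#'
#' @param profile a `disorder_profile` or numeric score vector.
#' @return fraction in \[0, 1\].
#' @export
disorder_content <- function(profile) {
  if (inherits(profile, "disorder_profile")) profile <- profile$scores
  mean(profile >= 0.5)
}

#' Disorder profiles for a set of proteins
#'
#' @param proteins named character vector of sequences.
#' @param predictor either `"builtin"` (default) or a named list of
#'   precomputed `disorder_profile` objects (e.g. from
#'   [read_score_track()]) covering every protein.
#' @param ... passed to [predict_disorder()] for the built-in predictor.
#' @return named list of `disorder_profile` objects.
#' @export
profile_set <- function(proteins, predictor = "builtin", ...) {
  if (is.list(predictor)) {
    miss <- setdiff(names(proteins), names(predictor))
    if (length(miss) > 0L) {
      stop("external predictor tracks missing for: ",
           paste(miss, collapse = ", "))
    }
    bad <- names(proteins)[vapply(names(proteins), function(id) {
      length(predictor[[id]]$scores) != nchar(proteins[[id]])
    }, logical(1))]
    if (length(bad) > 0L) {
      stop("track length does not match sequence length for: ",
           paste(bad, collapse = ", "))
    }
    return(predictor[names(proteins)])
  }
  out <- lapply(names(proteins), function(id) {
    predict_disorder(proteins[[id]], protein_id = id, ...)
  })
  setNames(out, names(proteins))
}
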