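#' Scan a disorder profile for alpha-MoRF candidate regions
#'
#' Stage 1 of the two-stage MoRF detector: find maximal runs of residues
#' called ordered (score < 0.5) whose length lies in
#' `[min_len, max_len]` and which are flanked on both sides by at least
#' `min_flank` consecutive residues called disordered — the "short
#' order-prone stretch inside long disorder" signature of a molecular
#' recognition feature. Runs touching a sequence terminus have no flank
#' on that side and are rejected. Candidates are disjoint and sorted by
#' start.
#'
#' @param profile a `disorder_profile`.
#' @param min_len,max_len bounds on the ordered stretch length (defaults
#'   5 and 25 residues).
#' @param min_flank minimum disordered flank on each side (default 10).
#' @return data.frame of candidates: `protein_id`, `start`, `end`
#'   (1-based inclusive, the ordered stretch only), `left_flank_len`,
#'   `right_flank_len`, `stage2_score` (NA until classified), `accepted`
#'   (TRUE until a stage-2 model says otherwise).
#' @export
scan_morf_candidates <- function(profile, min_len = 5L, max_len = 25L,
                                 min_flank = 10L) {
  stopifnot(min_len >= 1L, min_len <= max_len, min_flank >= 1L)
  scores <- if (inherits(profile, "disorder_profile")) profile$scores
            else as.numeric(profile)
  pid <- if (inherits(profile, "disorder_profile")) profile$protein_id
         else "seq"
  ordered <- scores < 0.5
  r <- rle(ordered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) next
    len <- r$lengths[i]
    if (len < min_len || len > max_len) next
    left <- if (i > 1L) r$lengths[i - 1L] else 0L
    right <- if (i < length(r$lengths)) r$lengths[i + 1L] else 0L
    if (left < min_flank || right < min_flank) next
    out[[length(out) + 1L]] <- data.frame(
      protein_id = pid, start = starts[i], end = ends[i],
      left_flank_len = left, right_flank_len = right,
      stage2_score = NA_real_, accepted = TRUE)
  }
  if (length(out) == 0L) {
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), left_flank_len = integer(),
                      right_flank_len = integer(),
                      stage2_score = numeric(), accepted = logical()))
  }
  do.call(rbind, out)
}

#' Feature vector for a stage-2 MoRF candidate
#'
#' Features: mean disorder score inside the ordered stretch, mean score
#' over both flanks, stretch length, left and right flank lengths, and
#' mean propensity-scale value of the stretch residues.
#'
#' @param candidate one-row candidate data.frame from
#'   [scan_morf_candidates()].
#' @param profile the `disorder_profile` the candidate came from.
#' @param sequence the protein sequence.
#' @param scale propensity scale (default TOP-IDP).
#' @return named numeric vector of 6 features.
#' @export
morf_features <- function(candidate, profile, sequence,
                          scale = propensity_scale()) {
  s <- candidate$start; e <- candidate$end
  scores <- profile$scores
  lf <- (s - candidate$left_flank_len):(s - 1L)
  rf <- (e + 1L):(e + candidate$right_flank_len)
  ch <- strsplit(substr(sequence, s, e), "")[[1]]
  c(stretch_ps = mean(scores[s:e]),
    flank_ps = mean(scores[c(lf, rf)]),
    stretch_len = e - s + 1,
    left_flank = candidate$left_flank_len,
    right_flank = candidate$right_flank_len,
    stretch_prop = mean(scale[ch], na.rm = TRUE))
}

#' Fit a two-class quadratic discriminant model
#'
#' Stage 2 of the MoRF detector: Gaussian class-conditional densities
#' with class-specific covariance matrices and empirical priors. A
#' covariance that is numerically singular is ridge-regularized by
#' adding `1e-6 * trace/dim` to its diagonal (with a warning).
#'
#' @param x numeric feature matrix (rows = candidates).
#' @param labels two-level factor or character/logical vector; the second
#'   level (or `TRUE`) is the positive (MoRF) class.
#' @return object of class `qd_model` (per-class means, covariances,
#'   priors).
#' @export
fit_qd <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("fit_qd needs exactly 2 classes")
  if (min(table(labels)) <= ncol(x)) {
    stop("each class needs more samples than features")
  }
  fit_class <- function(xi) {
    mu <- colMeans(xi)
    S <- stats::cov(xi)
    if (rcond_safe(S) < 1e-10) {
      warning("singular class covariance; ridge-regularizing")
      S <- S + diag(1e-6 * sum(diag(S)) / ncol(S), ncol(S))
    }
    list(mean = mu, cov = S)
  }
  parts <- lapply(levels(labels), function(l) fit_class(x[labels == l, , drop = FALSE]))
  structure(list(
    levels = levels(labels),
    means = lapply(parts, `[[`, "mean"),
    covs = lapply(parts, `[[`, "cov"),
    priors = as.numeric(table(labels) / length(labels)),
    features = colnames(x)),
    class = "qd_model")
}

rcond_safe <- function(S) {
  out <- tryCatch(rcond(S), error = function(e) 0)
  if (!is.finite(out)) 0 else out
}

log_mvn_density <- function(x, mu, S) {
  d <- length(mu)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    S <- S + diag(1e-6 * sum(diag(S)) / d, d)
    ch <- chol(S)
  }
  z <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

#' Classify candidates with a quadratic discriminant model
#'
#' @param model a `qd_model` from [fit_qd()].
#' @param x feature matrix (or single feature vector).
#' @return data.frame with `score` (log posterior odds of the positive
#'   class) and `accepted` (`score > 0`).
#' @export
classify_qd <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  score <- apply(x, 1, function(row) {
    lp <- vapply(1:2, function(k) {
      log(model$priors[k]) +
        log_mvn_density(row, model$means[[k]], model$covs[[k]])
    }, numeric(1))
    lp[2] - lp[1]
  })
  data.frame(score = score, accepted = score > 0)
}

#' Predict accepted MoRF regions for one protein
#'
#' Runs the stage-1 scan and, when a stage-2 model is supplied, scores
#' each candidate and keeps those with positive log posterior odds.
#' Without a model all stage-1 candidates are accepted.
#'
#' @param sequence protein sequence.
#' @param profile its `disorder_profile` (computed if omitted).
#' @param model optional `qd_model`.
#' @param min_len,max_len,min_flank stage-1 scan settings, see
#'   [scan_morf_candidates()].
#' @param scale propensity scale for the stage-2 features.
#' @param ... passed to [predict_disorder()] when the profile is
#'   computed here.
#' @return candidate data.frame with `stage2_score` and `accepted` filled
#'   in.
#' @export
predict_morfs <- function(sequence, profile = NULL, model = NULL,
                          min_len = 5L, max_len = 25L, min_flank = 10L,
                          scale = propensity_scale(), ...) {
  if (is.null(profile)) profile <- predict_disorder(sequence, ...)
  cand <- scan_morf_candidates(profile, min_len, max_len, min_flank)
  if (nrow(cand) == 0L || is.null(model)) return(cand)
  feats <- t(vapply(seq_len(nrow(cand)), function(i) {
    morf_features(cand[i, ], profile, sequence, scale)
  }, numeric(6)))
  res <- classify_qd(model, feats)
  cand$stage2_score <- res$score
  cand$accepted <- res$accepted
  cand
}

#' Per-mutation MoRF impact call
#'
#' Compares accepted MoRF regions of the wild-type and mutant profiles at
#' the mutated position: `lost` if a MoRF overlaps the position in the
#' wild type but none does in the mutant, `gained` for the reverse,
#' `present_no_change` if both, `absent` if neither. A MoRF overlaps the
#' position when the mutated residue lies within the ordered stretch
#' `[start, end]` (flanks excluded). `absent` mutations are excluded from
#' enrichment denominators downstream.
#'
#' @param wt_morfs,mut_morfs candidate data.frames (only rows with
#'   `accepted == TRUE` count).
#' @param position 1-based mutated position.
#' @return one of `"lost"`, `"gained"`, `"present_no_change"`,
#'   `"absent"`.
#' @export
classify_morf_impact <- function(wt_morfs, mut_morfs, position) {
  hits <- function(m) {
    nrow(m) > 0L && any(m$accepted & m$start <= position & m$end >= position)
  }
  wt <- hits(wt_morfs)
  mut <- hits(mut_morfs)
  if (wt && !mut) "lost"
  else if (!wt && mut) "gained"
  else if (wt && mut) "present_no_change"
  else "absent"
}

#' MoRF impact calls for a full mutation table
#'
#' @param mutations validated mutation data.frame.
#' @param proteins named sequence vector.
#' @param model optional stage-2 `qd_model`.
#' @param ... passed to [predict_morfs()] (scan settings and predictor
#'   settings).
#' @return `mutations` with an added `morf_impact` column.
#' @export
morf_impact_dataset <- function(mutations, proteins, model = NULL, ...) {
  wt_morfs <- lapply(setNames(nm = unique(mutations$protein_id)), function(id) {
    predict_morfs(proteins[[id]], model = model, ...)
  })
  impact <- vapply(seq_len(nrow(mutations)), function(i) {
    m <- mutations[i, ]
    seq <- proteins[[m$protein_id]]
    mutated <- seq
    substr(mutated, m$position, m$position) <- m$mut_aa
    mm <- predict_morfs(mutated, model = model, ...)
    classify_morf_impact(wt_morfs[[m$protein_id]], mm, m$position)
  }, character(1))
  mutations$morf_impact <- impact
  mutations
}
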