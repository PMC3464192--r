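TRANSITION_CLASSES <- c("D->O", "O->D", "D->D", "O->O")

#' Classify a mutation by order/disorder transition
#'
#' The class is a function of the disorder scores of the mutated residue
#' only, under the 0.5 threshold: a D->O (disorder-to-order) transition
#' means the wild-type score was >= 0.5 and the mutant score < 0.5; O->D
#' is the reverse; D->D and O->O preserve the call. Vectorized.
#'
#' @param wt_ps,mut_ps scores in \[0, 1\] at the mutated residue in the
#'   wild-type and mutant profiles.
#' @return factor with levels `D->O`, `O->D`, `D->D`, `O->O`.
#' @examples
#' classify_transition(0.7, 0.3)   # D->O
#' classify_transition(0.5, 0.5)   # D->D (0.5 itself is disordered)
#' @export
classify_transition <- function(wt_ps, mut_ps) {
  if (any(wt_ps < 0 | wt_ps > 1 | mut_ps < 0 | mut_ps > 1)) {
    stop("scores must lie in [0,1]")
  }
  wt_d <- wt_ps >= 0.5
  mut_d <- mut_ps >= 0.5
  klass <- ifelse(wt_d & !mut_d, "D->O",
           ifelse(!wt_d & mut_d, "O->D",
           ifelse(wt_d & mut_d, "D->D", "O->O")))
  factor(klass, levels = TRANSITION_CLASSES)
}

#' Score at the mutated residue of the mutant sequence
#'
#' Recomputes the full mutant profile and extracts the mutated position.
#'
#' @inheritParams predict_mutant
#' @return numeric score in \[0, 1\].
#' @export
mutant_score <- function(sequence, position, mut_aa, ...) {
  predict_mutant(sequence, position, mut_aa, ...)$scores[as.integer(position)]
}

#' Classify every mutation in a dataset
#'
#' Produces one transition call per mutation: wild-type and mutant scores
#' at the mutated residue, the transition class, and
#' `delta_ps = ps(WT) - ps(mutant)`. For the built-in predictor mutant
#' sequences are rescored full-length; for external score tracks a mutant
#' profile per mutation must be supplied.
#'
#' @param mutations validated mutation data.frame (see
#'   [validate_mutations()]).
#' @param proteins named character vector of sequences.
#' @param predictor `"builtin"`, or a named list of wild-type
#'   `disorder_profile` objects (external scores).
#' @param mutant_profiles for external predictors: a list of mutant
#'   profiles indexed by `"protein_id:position:mut_aa"`.
#' @param ... passed to [predict_disorder()] (built-in predictor only).
#' @return data.frame with one row per mutation (columns `protein_id`,
#'   `position`, `wt_aa`, `mut_aa`, `dataset`, `wt_ps`, `mut_ps`,
#'   `class`, `delta_ps`).
#' @export
classify_dataset <- function(mutations, proteins, predictor = "builtin",
                             mutant_profiles = NULL, ...) {
  wt_prof <- profile_set(proteins, predictor, ...)
  ids <- unique(mutations$protein_id)
  wt_ps <- mapply(function(id, pos) wt_prof[[id]]$scores[pos],
                  mutations$protein_id, mutations$position)
  if (is.list(predictor)) {
    key <- paste(mutations$protein_id, mutations$position,
                 mutations$mut_aa, sep = ":")
    if (is.null(mutant_profiles) || !all(key %in% names(mutant_profiles))) {
      stop("mutant scores required: external predictors need a mutant ",
           "profile per mutation")
    }
    mut_ps <- mapply(function(k, pos) mutant_profiles[[k]]$scores[pos],
                     key, mutations$position)
  } else {
    mut_ps <- mapply(function(id, pos, aa) {
      mutant_score(proteins[[id]], pos, aa, ...)
    }, mutations$protein_id, mutations$position, mutations$mut_aa)
  }
  calls <- mutations
  calls$wt_ps <- unname(wt_ps)
  calls$mut_ps <- unname(mut_ps)
  calls$class <- classify_transition(calls$wt_ps, calls$mut_ps)
  calls$delta_ps <- calls$wt_ps - calls$mut_ps
  rownames(calls) <- NULL
  calls
}

#' Per-dataset transition class counts
#'
#' @param calls output of [classify_dataset()].
#' @return data.frame with one row per dataset and columns `D->O`,
#'   `O->D`, `D->D`, `O->O`, `n`.
#' @export
transition_counts <- function(calls) {
  tab <- table(calls$dataset, calls$class)
  out <- as.data.frame.matrix(tab)
  out <- cbind(dataset = rownames(out), out, n = rowSums(out))
  rownames(out) <- NULL
  out
}

#' Transition enrichment tables between a case and a control dataset
#'
#' Builds the two 2x2 tables used for enrichment testing: among IDR
#' mutations (wild-type call disordered) D->O vs D->D, and among OR
#' mutations O->D vs O->O, case dataset vs control dataset.
#'
#' @param counts output of [transition_counts()].
#' @param case,control dataset labels.
#' @return list with `idr` and `or` 2x2 integer matrices (rows = case,
#'   control; columns = transition, no transition).
#' @export
transition_tables <- function(counts, case, control) {
  row_for <- function(ds) counts[counts$dataset == ds, , drop = FALSE]
  a <- row_for(case); b <- row_for(control)
  if (nrow(a) != 1L || nrow(b) != 1L) stop("dataset not found in counts")
  idr <- matrix(c(a[["D->O"]], a[["D->D"]], b[["D->O"]], b[["D->D"]]),
                nrow = 2, byrow = TRUE,
                dimnames = list(c(case, control), c("D->O", "D->D")))
  or <- matrix(c(a[["O->D"]], a[["O->O"]], b[["O->D"]], b[["O->O"]]),
               nrow = 2, byrow = TRUE,
               dimnames = list(c(case, control), c("O->D", "O->O")))
  list(idr = idr, or = or)
}

#' Summaries of the delta-ps distribution
#'
#' Reports, per dataset, the observed range of
#' `delta_ps = ps(WT) - ps(mutant)`, the fraction of mutations in the
#' distribution tails, and the unbiased sample excess kurtosis (a more
#' platykurtic, i.e. lower-kurtosis, distribution has relatively heavier
#' shoulders — more mutations causing large score changes).
#'
#' @param calls output of [classify_dataset()] (needs >= 4 calls per
#'   dataset for the kurtosis estimator).
#' @param cutoffs absolute delta-ps tail cutoffs; default 0.2.
#' @return data.frame per dataset: `n`, `min`, `max`, one
#'   `tail_frac_<cutoff>` column per cutoff, `excess_kurtosis`.
#' @export
delta_ps_summary <- function(calls, cutoffs = 0.2) {
  do.call(rbind, lapply(split(calls, calls$dataset), function(d) {
    x <- d$delta_ps
    if (length(x) < 4L) stop("need >= 4 calls per dataset for kurtosis")
    tails <- vapply(cutoffs, function(ct) mean(abs(x) >= ct), numeric(1))
    out <- data.frame(dataset = d$dataset[1], n = length(x),
                      min = min(x), max = max(x))
    for (i in seq_along(cutoffs)) {
      out[[paste0("tail_frac_", cutoffs[i])]] <- tails[i]
    }
    out$excess_kurtosis <- excess_kurtosis(x)
    out
  }))
}

#' Unbiased sample excess kurtosis
#'
#' The bias-corrected estimator; approaches 0 for normal samples and -2
#' for a balanced two-point distribution.
#'
#' @param x numeric vector, length >= 4, non-constant.
#' @return numeric scalar.
#' @export
excess_kurtosis <- function(x) {
  n <- length(x)
  if (n < 4L) stop("need n >= 4")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NaN)
  g2 <- mean((x - m)^4) / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

#' Secondary-structure transition counts
#'
#' Tallies per-mutation wild-type -> mutant secondary-structure state
#' changes (helix H, strand E, loop L) at the mutated residue, keeping
#' only reliable predictions: both the "from" and the "to" assignment
#' must have reliability at or above `reliability_min`. Excluded pairs
#' are counted, so the table total plus exclusions equals the input size.
#'
#' @param pairs data.frame with columns `dataset`, `wt_state`,
#'   `mut_state`, `wt_rel`, `mut_rel`.
#' @param reliability_min minimum reliability score (default 4).
#' @return list per dataset: `counts` (3x3 integer matrix H/E/L) and
#'   `excluded` (number of pairs failing the reliability filter).
#' @export
ss_transitions <- function(pairs, reliability_min = 4L) {
  states <- c("H", "E", "L")
  if (!all(pairs$wt_state %in% states & pairs$mut_state %in% states)) {
    stop("unknown secondary-structure state (expected H, E or L)")
  }
  lapply(split(pairs, pairs$dataset), function(d) {
    keep <- d$wt_rel >= reliability_min & d$mut_rel >= reliability_min
    kept <- d[keep, , drop = FALSE]
    counts <- table(factor(kept$wt_state, states),
                    factor(kept$mut_state, states))
    list(counts = unclass(as.matrix(counts)), excluded = sum(!keep))
  })
}

#' Wild-type to mutant substitution count matrix
#'
#' 20x20 integer counts of wild-type residue (rows) to mutant residue
#' (columns) for a stratum of calls, with rows/columns arranged by the
#' Vihinen flexibility ordering (the customary heat-map layout) or
#' alphabetically. The diagonal is structurally zero.
#'
#' @param calls output of [classify_dataset()].
#' @param dataset optional dataset label filter.
#' @param class optional transition class filter (e.g. `"D->O"`).
#' @param ordering `"vihinen"` or `"alphabetical"`.
#' @return 20x20 integer matrix with residue dimnames.
#' @export
substitution_matrix <- function(calls, dataset = NULL, class = NULL,
                                ordering = "vihinen") {
  d <- calls
  if (!is.null(dataset)) d <- d[d$dataset %in% dataset, , drop = FALSE]
  if (!is.null(class)) d <- d[as.character(d$class) %in% class, , drop = FALSE]
  ord <- residue_order(ordering)
  tab <- table(factor(d$wt_aa, ord), factor(d$mut_aa, ord))
  m <- unclass(as.matrix(tab))
  storage.mode(m) <- "integer"
  m
}

#' Element-wise percent difference between two substitution matrices
#'
#' Each matrix is first converted to percentages of its own total; the
#' result is the element-wise difference (positive = enriched in the
#' first stratum).
#'
#' @param m_case,m_control count matrices from [substitution_matrix()].
#' @return numeric matrix of percentage-point differences.
#' @export
substitution_matrix_diff <- function(m_case, m_control) {
  100 * m_case / sum(m_case) - 100 * m_control / sum(m_control)
}

#' Mutation rates per ordered and disordered residue
#'
#' For each dataset, the rate in a region type is the number of mutations
#' whose wild-type residue is called in that region divided by the total
#' number of residues of that type over the dataset's proteins.
#'
#' @param mutations validated mutation data.frame.
#' @param profiles named list of wild-type `disorder_profile` objects
#'   covering every protein carrying mutations.
#' @return data.frame: `dataset`, `region` (IDR/OR), `mutations`,
#'   `residues`, `rate`.
#' @export
mutation_rates <- function(mutations, profiles) {
  if (nrow(mutations) == 0L) {
    return(data.frame(dataset = character(), region = character(),
                      mutations = integer(), residues = integer(),
                      rate = numeric()))
  }
  do.call(rbind, lapply(split(mutations, mutations$dataset), function(d) {
    ids <- unique(d$protein_id)
    miss <- setdiff(ids, names(profiles))
    if (length(miss) > 0L) {
      stop("profiles missing for: ", paste(miss, collapse = ", "))
    }
    dis_res <- sum(vapply(ids, function(id) {
      sum(profiles[[id]]$scores >= 0.5)
    }, numeric(1)))
    tot_res <- sum(vapply(ids, function(id) {
      length(profiles[[id]]$scores)
    }, numeric(1)))
    wt_dis <- mapply(function(id, pos) profiles[[id]]$scores[pos] >= 0.5,
                     d$protein_id, d$position)
    n_idr <- sum(wt_dis)
    n_or <- sum(!wt_dis)
    data.frame(
      dataset = d$dataset[1],
      region = c("IDR", "OR"),
      mutations = c(n_idr, n_or),
      residues = c(dis_res, tot_res - dis_res),
      rate = c(if (dis_res > 0) n_idr / dis_res else 0,
               if (tot_res - dis_res > 0) n_or / (tot_res - dis_res) else 0))
  }))
}
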