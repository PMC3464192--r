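#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test with the point-probability two-sided
#' convention: the p-value sums the probabilities of all tables with the
#' same margins whose point probability does not exceed that of the
#' observed table (within a small relative slack guarding floating-point
#' ties).
#'
#' @param table 2x2 non-negative integer matrix (or a length-4 vector
#'   `c(a, b, c, d)` filled by row), with at least one positive count.
#' @return two-sided p-value in (0, 1\].
#' @examples
#' fisher_exact_2x2(c(670, 2686, 1125, 8665))  # ~1e-32
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as_2x2(table)
  stats::fisher.test(tab)$p.value
}

as_2x2 <- function(table) {
  if (is.null(dim(table))) {
    if (length(table) != 4L) stop("need a 2x2 table")
    table <- matrix(table, nrow = 2, byrow = TRUE)
  }
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  if (sum(table) == 0) stop("all-zero table")
  table
}

#' Bonferroni multiple-testing correction
#'
#' Each p-value is multiplied by the number of tests and capped at 1.
#' The correction family should be all tests performed within one
#' analysis.
#'
#' @param p_values numeric vector of raw p-values in (0, 1\].
#' @return adjusted p-values, same order.
#' @export
bonferroni <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0,1]")
  p.adjust(p_values, method = "bonferroni")
}

#' Fold difference between two proportions with a standard error
#'
#' For a 2x2 table `rbind(c(a, b), c(c, d))` comparing event proportions
#' between two groups, the fold is `(a/(a+b)) / (c/(c+d))` and its
#' standard error comes from the delta method on the log ratio:
#' `fold * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`.
#'
#' @param table 2x2 matrix or `c(a, b, c, d)` by row.
#' @return list with `fold` and `fold_se`; both `NA` (with a warning)
#'   when either proportion is zero.
#' @export
fold_difference <- function(table) {
  tab <- as_2x2(table)
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  p1 <- a / (a + b); p2 <- cc / (cc + d)
  if (is.nan(p1) || is.nan(p2) || p1 == 0 || p2 == 0) {
    warning("fold undefined: a zero proportion")
    return(list(fold = NA_real_, fold_se = NA_real_))
  }
  fold <- p1 / p2
  se <- fold * sqrt(1 / a - 1 / (a + b) + 1 / cc - 1 / (cc + d))
  list(fold = fold, fold_se = se)
}

#' Full enrichment result for a 2x2 table
#'
#' @param table 2x2 matrix or `c(a, b, c, d)` by row.
#' @param test_count size of the Bonferroni family (default 1).
#' @param label optional stratum label.
#' @return data.frame row: counts, `fold`, `fold_se`, `p_raw`, `p_adj`,
#'   `test_count`.
#' @export
enrichment_result <- function(table, test_count = 1L, label = "") {
  tab <- as_2x2(table)
  fd <- suppressWarnings(fold_difference(tab))
  p <- fisher_exact_2x2(tab)
  data.frame(label = label, a = tab[1, 1], b = tab[1, 2],
             c = tab[2, 1], d = tab[2, 2],
             fold = fd$fold, fold_se = fd$fold_se,
             p_raw = p, p_adj = min(1, p * test_count),
             test_count = as.integer(test_count))
}

#' Residue composition profile against a background
#'
#' Per-residue fractional difference
#' `(f_sample - f_background) / f_background`, where `f` are
#' composition fractions, with a bootstrap standard error: the sample
#' counts are resampled `reps` times from a multinomial with the
#' observed sample fractions and the statistic's standard deviation is
#' reported per residue. A residue absent from the sample but present in
#' the background scores exactly -1.
#'
#' @param sample_counts,background_counts named 20-entry count vectors
#'   over the canonical residues.
#' @param reps bootstrap replicates (default 10000).
#' @param seed integer seed; resampling is bit-reproducible given the
#'   seed.
#' @return data.frame: `res`, `diff`, `se`, plus attributes `reps` and
#'   `seed`.
#' @export
composition_profile <- function(sample_counts, background_counts,
                                reps = 10000L, seed = 1L) {
  if (reps < 100L) stop("reps must be >= 100")
  s <- complete_counts(sample_counts)
  b <- complete_counts(background_counts)
  fb <- b / sum(b)
  if (any(fb == 0 & s > 0)) {
    stop("background frequency zero for a residue present in the sample")
  }
  fs <- s / sum(s)
  diff <- ifelse(fb > 0, (fs - fb) / fb, NA_real_)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  boots <- rmultinom(reps, sum(s), fs)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  bf <- sweep(boots, 2, colSums(boots), "/")
  stat <- sweep(sweep(bf, 1, fb, "-"), 1, fb, "/")
  se <- apply(stat, 1, sd)
  out <- data.frame(res = AA20, diff = unname(diff), se = unname(se))
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  out
}

complete_counts <- function(counts) {
  if (is.null(names(counts))) {
    if (length(counts) != 20L) stop("need named counts or 20 entries")
    names(counts) <- AA20
  }
  out <- setNames(numeric(20), AA20)
  out[names(counts)] <- counts
  if (any(out < 0)) stop("negative counts")
  out
}

FT_PREFIXES <- c("Required for", "Sufficient for", "Essential for",
                 "Essential to", "Important for", "Critical for",
                 "Necessary for", "Involved in", "Mediates", "For")

#' Normalize feature annotations
#'
#' Applies the feature-table curation rules: annotations qualified as
#' `Potential`, `Probable` or `By similarity` are dropped; level-1
#' features are the bare keywords; level-2 features concatenate the
#' keyword with the description after stripping leading qualifier
#' prefixes ("Required for", "Involved in", ..., longest prefix first,
#' case-insensitive) and collapsing whitespace; features observed fewer
#' than `min_count` times in the reference dataset are removed, as are
#' disease-named keywords (trivially enriched in a disease set).
#'
#' @param annotations data.frame from [read_annotations()], with a
#'   `dataset` column when the reference-count filter should apply.
#' @param min_count minimum occurrences in the reference dataset
#'   (default 5).
#' @param count_dataset reference dataset label (default `"DM"`); when
#'   absent from the data the filter counts all rows.
#' @param disease_keys keywords removed outright (default `"Disease"`).
#' @param prefixes prefix list to strip from descriptions.
#' @return the surviving annotations with added `level1` and `level2`
#'   columns.
#' @export
normalize_ft <- function(annotations, min_count = 5L,
                         count_dataset = "DM",
                         disease_keys = "Disease",
                         prefixes = FT_PREFIXES) {
  a <- annotations
  a <- a[!a$qualifier %in% c("Potential", "Probable", "By similarity"), ,
         drop = FALSE]
  a <- a[!a$key %in% disease_keys, , drop = FALSE]
  a$level1 <- a$key
  a$level2 <- paste(a$key, strip_prefixes(a$description, prefixes))
  a$level2 <- trimws(gsub("\\s+", " ", a$level2))
  ref <- if (!is.null(a$dataset) && count_dataset %in% a$dataset) {
    a[a$dataset == count_dataset, , drop = FALSE]
  } else {
    a
  }
  keep2 <- names(which(table(ref$level2) >= min_count))
  a <- a[a$level2 %in% keep2, , drop = FALSE]
  rownames(a) <- NULL
  a
}

strip_prefixes <- function(x, prefixes) {
  prefixes <- prefixes[order(-nchar(prefixes))]
  for (p in prefixes) {
    x <- sub(paste0("^\\s*", p, "\\b\\s*"), "", x, ignore.case = TRUE)
  }
  trimws(x)
}

#' Feature enrichment between two mutation strata
#'
#' For each normalized feature, builds the 2x2 table of mutations
#' overlapping at least one instance of the feature versus not, in
#' stratum A versus stratum B, and reports the Fisher p-value
#' (Bonferroni-corrected over all features tested), the fold difference
#' of overlap proportions with its standard error, sorted by decreasing
#' fold. Features overlapped by no mutation in either stratum are
#' excluded from the family.
#'
#' @param annotations normalized annotations (see [normalize_ft()]).
#' @param mutations mutation data.frame with a `stratum` column.
#' @param stratum_a,stratum_b stratum labels to compare (e.g. `"IDR"`
#'   vs `"OR"`).
#' @param level `"level1"` or `"level2"`.
#' @return data.frame of enrichment rows, one per feature.
#' @export
ft_enrichment <- function(annotations, mutations, stratum_a, stratum_b,
                          level = c("level2", "level1")) {
  level <- match.arg(level)
  ma <- mutations[mutations$stratum == stratum_a, , drop = FALSE]
  mb <- mutations[mutations$stratum == stratum_b, , drop = FALSE]
  feats <- unique(annotations[[level]])
  rows <- lapply(feats, function(f) {
    ann <- annotations[annotations[[level]] == f, , drop = FALSE]
    a <- sum(overlaps_any(ma, ann))
    b <- nrow(ma) - a
    cc <- sum(overlaps_any(mb, ann))
    d <- nrow(mb) - cc
    if (a + cc == 0L) return(NULL)
    enrichment_result(c(a, b, cc, d), test_count = 1L, label = f)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  out$test_count <- nrow(out)
  out$p_adj <- pmin(1, out$p_raw * out$test_count)
  out[order(-out$fold), , drop = FALSE]
}

overlaps_any <- function(mutations, intervals) {
  if (nrow(mutations) == 0L) return(logical(0))
  vapply(seq_len(nrow(mutations)), function(i) {
    any(intervals$protein_id == mutations$protein_id[i] &
          intervals$start <= mutations$position[i] &
          intervals$end >= mutations$position[i])
  }, logical(1))
}

#' Mutation overlap with annotated intervals
#'
#' A mutation overlaps an interval when its position falls inside the
#' 1-based inclusive `[start, end]` range on the same protein. Overlap
#' counts are stratified by dataset and transition class, and every
#' stratum is compared to every other by a Fisher test on overlapping
#' versus non-overlapping counts.
#'
#' @param calls transition calls (output of [classify_dataset()]), or
#'   any mutation data.frame with optional `class` column.
#' @param intervals data.frame with `protein_id`, `start`, `end`.
#' @return list: `counts` (per dataset x class: n, overlapping) and
#'   `tests` (pairwise Fisher comparisons between datasets within each
#'   class).
#' @export
interval_overlap <- function(calls, intervals) {
  hit <- overlaps_any(calls, intervals)
  klass <- if (is.null(calls$class)) rep("all", nrow(calls))
           else as.character(calls$class)
  counts <- aggregate(data.frame(n = rep(1L, nrow(calls)),
                                 overlapping = as.integer(hit)),
                      by = list(dataset = calls$dataset, class = klass),
                      FUN = sum)
  tests <- list()
  for (cl in unique(counts$class)) {
    sub <- counts[counts$class == cl, , drop = FALSE]
    if (nrow(sub) < 2L) next
    for (i in 1:(nrow(sub) - 1L)) {
      for (j in (i + 1L):nrow(sub)) {
        tab <- c(sub$overlapping[i], sub$n[i] - sub$overlapping[i],
                 sub$overlapping[j], sub$n[j] - sub$overlapping[j])
        lbl <- paste(cl, sub$dataset[i], "vs", sub$dataset[j])
        tests[[lbl]] <- enrichment_result(tab, label = lbl)
      }
    }
  }
  list(counts = counts,
       tests = if (length(tests)) do.call(rbind, tests) else data.frame())
}

#' Stratified evaluation of external predictor calls
#'
#' Given one categorical call per mutation from an external
#' deleteriousness predictor, reports the fraction of each call category
#' per stratum (IDR/OR region and the four transition classes), with a
#' 2x2 Fisher comparison of each category between region strata.
#' `"unknown"` calls are tabulated separately but kept in the
#' denominators, so fractions sum to 1 within each stratum.
#'
#' @param calls transition calls with a `call` column (the external
#'   predictor's category per mutation).
#' @return list: `fractions` (stratum x category), `tests` (per
#'   category, IDR vs OR Fisher comparison), `unknown` (count per
#'   stratum).
#' @export
stratified_calls <- function(calls) {
  if (is.null(calls$call)) stop("calls need a 'call' column")
  region <- ifelse(calls$wt_ps >= 0.5, "IDR", "OR")
  strata <- c(split(calls$call, region),
              split(calls$call, as.character(calls$class)))
  cats <- sort(unique(calls$call))
  fractions <- matrix(NA_real_, length(strata), length(cats),
                      dimnames = list(names(strata), cats))
  for (s in names(strata)) {
    fractions[s, ] <- as.numeric(table(factor(strata[[s]], cats))) /
      length(strata[[s]])
  }
  tests <- do.call(rbind, lapply(cats, function(ct) {
    a <- sum(calls$call == ct & region == "IDR")
    b <- sum(calls$call != ct & region == "IDR")
    cc <- sum(calls$call == ct & region == "OR")
    d <- sum(calls$call != ct & region == "OR")
    if (a + cc == 0L) return(NULL)
    enrichment_result(c(a, b, cc, d), label = paste(ct, "IDR vs OR"))
  }))
  unknown <- vapply(strata, function(x) sum(x == "unknown"), numeric(1))
  list(fractions = fractions, tests = tests, unknown = unknown)
}
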