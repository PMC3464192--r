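#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate
#' the structure the analysis assumes: proteins with alternating
#' ordered/disordered block architecture and composition bias, three
#' mutation datasets (disease-like DM, polymorphism-like Poly,
#' neutral-substitution-like NES) with planted disorder-to-order
#' transition probabilities of 0.2 for DM versus 0.1 for both controls
#' (a planted enrichment fold of 2), and region/residue feature
#' annotations placed on disordered blocks at 3:1 odds.
#'
#' @param n_proteins number of proteins (default 60).
#' @param len_min,len_max uniform bounds on protein length (80, 400).
#' @param mean_disordered_block,mean_ordered_block geometric mean block
#'   lengths in residues (both 40).
#' @param beta composition bias strength (>= 0): residues are drawn with
#'   probability proportional to `exp(+/- beta * z)` where `z` is the
#'   standardized propensity and the sign follows the block type.
#'   Default 2.
#' @param morf_density probability that a long disordered block carries
#'   an embedded order-prone (MoRF-like) stretch (default 0.15).
#' @param datasets named list; each element has `n` (mutation count) and
#'   planted per-mutation transition probabilities `p_do`, `p_od`.
#' @param annotation list: `n_features`, `odds` (placement odds for
#'   disordered over ordered blocks), `mean_len` (feature length).
#' @param window,steepness built-in predictor settings used when
#'   planting score-flipping mutations.
#' @param seed root seed for all generator randomness.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 60L, len_min = 80L, len_max = 400L,
                       mean_disordered_block = 40, mean_ordered_block = 40,
                       beta = 2, morf_density = 0.15,
                       datasets = list(
                         DM = list(n = 1500L, p_do = 0.2, p_od = 0.05),
                         Poly = list(n = 1500L, p_do = 0.1, p_od = 0.05),
                         NES = list(n = 1500L, p_do = 0.1, p_od = 0.05)),
                       annotation = list(n_features = 150L, odds = 3,
                                         mean_len = 10),
                       window = 21L, steepness = 8, seed = 42L) {
  stopifnot(n_proteins >= 1L, len_min >= 1L, len_min <= len_max,
            mean_disordered_block > 0, mean_ordered_block > 0,
            beta >= 0, morf_density >= 0, morf_density <= 1)
  for (d in datasets) {
    stopifnot(d$n >= 0L, d$p_do >= 0, d$p_do <= 1, d$p_od >= 0,
              d$p_od <= 1, d$p_do + d$p_od <= 1)
  }
  structure(as.list(environment()), class = "sim_config")
}

# uniform draw from a vector, immune to the sample() scalar expansion
sample_one <- function(v) v[sample.int(length(v), 1L)]

block_weights <- function(scale, beta, type) {
  z <- (scale - mean(scale)) / sd(scale)
  w <- exp(if (type == "D") beta * z else -beta * z)
  w / sum(w)
}

#' Generate synthetic proteins with known order/disorder architecture
#'
#' Sequences are built from alternating ordered and disordered blocks
#' (geometric lengths, first type random per protein). Residues are
#' drawn with probability proportional to `exp(+beta * z)` in disordered
#' blocks and `exp(-beta * z)` in ordered blocks (`z` = standardized
#' TOP-IDP propensity), so disordered blocks are enriched in
#' disorder-promoting residues. Long disordered blocks may carry an
#' embedded MoRF-like order-prone stretch at the configured density.
#'
#' @param config a `sim_config`.
#' @return list: `proteins` (named sequence vector), `labels` (named
#'   list of per-residue `"D"`/`"O"` truth labels), `morfs` (data.frame
#'   of planted MoRF-like stretches).
#' @export
gen_proteins <- function(config) {
  set.seed(config$seed)
  scale <- propensity_scale()
  wD <- block_weights(scale, config$beta, "D")
  wO <- block_weights(scale, config$beta, "O")
  strong_order <- c("W", "F", "Y", "I")
  proteins <- character(config$n_proteins)
  labels <- vector("list", config$n_proteins)
  morfs <- list()
  ids <- sprintf("sp%03d", seq_len(config$n_proteins))
  for (p in seq_len(config$n_proteins)) {
    len <- sample_one(config$len_min:config$len_max)
    type <- sample(c("D", "O"), 1L)
    res <- character(0)
    lab <- character(0)
    while (length(res) < len) {
      mean_len <- if (type == "D") config$mean_disordered_block
                  else config$mean_ordered_block
      bl <- min(rgeom(1L, 1 / mean_len) + 1L, len - length(res))
      w <- if (type == "D") wD else wO
      block <- sample(AA20, bl, replace = TRUE, prob = w)
      if (type == "D" && bl >= 31L &&
          runif(1L) < config$morf_density) {
        mlen <- sample_one(8:min(15L, bl - 23L))
        off <- sample_one(12:(bl - mlen - 11L))
        block[off:(off + mlen - 1L)] <-
          sample(strong_order, mlen, replace = TRUE)
        morfs[[length(morfs) + 1L]] <- data.frame(
          protein_id = ids[p], start = length(res) + off,
          end = length(res) + off + mlen - 1L)
      }
      res <- c(res, block)
      lab <- c(lab, rep(type, bl))
      type <- if (type == "D") "O" else "D"
    }
    proteins[p] <- paste(res, collapse = "")
    labels[[p]] <- lab
  }
  names(proteins) <- names(labels) <- ids
  list(proteins = proteins, labels = labels,
       morfs = if (length(morfs)) do.call(rbind, morfs)
               else data.frame(protein_id = character(),
                               start = integer(), end = integer()))
}

#' Generate mutation datasets with planted transition probabilities
#'
#' Each dataset draws its configured number of mutations. A mutation is
#' planted as D->O with probability `p_do`: a site currently called
#' disordered by the built-in predictor is chosen and the wild-type
#' residue replaced by a more order-promoting residue that flips the
#' call at that site (rejection sampling over sites and candidate
#' residues, bounded retries; failures fall back to a background
#' mutation and are counted). O->D planting is symmetric. Background
#' mutations substitute a uniformly chosen different residue at a
#' uniformly chosen site — these can still flip calls accidentally,
#' which is the measured baseline, not an error.
#'
#' @param proteins named sequence vector from [gen_proteins()].
#' @param labels per-residue truth labels (unused by the sampler but
#'   carried for symmetry with the generator interface).
#' @param config a `sim_config`.
#' @return list: `mutations` (data.frame ready for
#'   [classify_dataset()]), `truth` (same rows plus the `intended`
#'   class: `"D->O"`, `"O->D"` or `"background"`), `plant_failures`
#'   (named counts per dataset).
#' @export
gen_mutations <- function(proteins, labels, config) {
  set.seed(config$seed + 1L)
  scale <- propensity_scale()
  mid <- mean(scale)
  props <- lapply(proteins, residue_propensities, scale = scale)
  profs <- lapply(props, function(pr) {
    plogis(config$steepness * (windowed_mean(pr, config$window) - mid))
  })
  lens <- nchar(proteins)
  ids <- names(proteins)
  prot_w <- lens / sum(lens)

  ps_after <- function(id, pos, new_res) {
    pr <- props[[id]]
    pr[pos] <- scale[[new_res]]
    wm <- windowed_mean(pr, config$window)
    plogis(config$steepness * (wm[pos] - mid))
  }

  plant <- function(id_pool_fun, flip_test, cand_fun, max_tries = 40L) {
    for (try in seq_len(max_tries)) {
      id <- sample(ids, 1L, prob = prot_w)
      sites <- id_pool_fun(id)
      if (length(sites) == 0L) next
      pos <- sites[sample.int(length(sites), 1L)]
      wt <- substr(proteins[[id]], pos, pos)
      cands <- cand_fun(wt)
      if (length(cands) == 0L) next
      for (mut in sample(cands, length(cands))) {
        if (flip_test(ps_after(id, pos, mut))) {
          return(list(id = id, pos = pos, wt = wt, mut = mut))
        }
      }
    }
    NULL
  }

  all_mut <- list()
  all_truth <- character(0)
  failures <- setNames(integer(length(config$datasets)),
                       names(config$datasets))
  for (ds in names(config$datasets)) {
    cfg <- config$datasets[[ds]]
    recs <- vector("list", cfg$n)
    intended <- character(cfg$n)
    for (i in seq_len(cfg$n)) {
      u <- runif(1L)
      hit <- NULL
      if (u < cfg$p_do) {
        hit <- plant(
          function(id) which(profs[[id]] >= 0.5),
          function(ps) ps < 0.5,
          function(wt) AA20[scale < scale[[wt]]])
        intended[i] <- "D->O"
      } else if (u < cfg$p_do + cfg$p_od) {
        hit <- plant(
          function(id) which(profs[[id]] < 0.5),
          function(ps) ps >= 0.5,
          function(wt) AA20[scale > scale[[wt]]])
        intended[i] <- "O->D"
      }
      if (is.null(hit)) {
        if (intended[i] != "") failures[ds] <- failures[ds] + 1L
        intended[i] <- "background"
        id <- sample(ids, 1L, prob = prot_w)
        pos <- sample.int(lens[[id]], 1L)
        wt <- substr(proteins[[id]], pos, pos)
        mut <- sample(setdiff(AA20, wt), 1L)
        hit <- list(id = id, pos = pos, wt = wt, mut = mut)
      }
      recs[[i]] <- data.frame(protein_id = hit$id, position = hit$pos,
                              wt_aa = hit$wt, mut_aa = hit$mut,
                              dataset = ds)
    }
    all_mut[[ds]] <- do.call(rbind, recs)
    all_truth <- c(all_truth, intended)
  }
  mutations <- do.call(rbind, all_mut)
  rownames(mutations) <- NULL
  truth <- mutations
  truth$intended <- all_truth
  list(mutations = mutations, truth = truth, plant_failures = failures)
}

SIM_FT_KEYS <- c("DNA_BIND", "ZN_FING", "TRANSMEM", "MOD_RES",
                 "DISULFID", "REGION")

#' Generate feature annotations with planted enrichment
#'
#' Features are placed on sequence blocks with odds
#' `odds : 1` (disordered : ordered), weighted by block length, so the
#' per-residue feature coverage of disordered regions exceeds that of
#' ordered regions by approximately the configured odds (exactly, before
#' overlap saturation). Keys rotate through a small UniProt-style
#' keyword pool.
#'
#' @param proteins named sequence vector.
#' @param labels per-residue truth labels from [gen_proteins()].
#' @param config a `sim_config`.
#' @return annotation data.frame (`protein_id`, `start`, `end`, `key`,
#'   `description`, `qualifier`) with the chosen block type recorded in
#'   a `placed_on` column as ground truth.
#' @export
gen_annotations <- function(proteins, labels, config) {
  set.seed(config$seed + 2L)
  acfg <- config$annotation
  blocks <- do.call(rbind, lapply(names(labels), function(id) {
    r <- rle(labels[[id]])
    ends <- cumsum(r$lengths)
    data.frame(protein_id = id, start = ends - r$lengths + 1L,
               end = ends, type = r$values)
  }))
  blen <- blocks$end - blocks$start + 1L
  w <- blen * ifelse(blocks$type == "D", acfg$odds, 1)
  out <- lapply(seq_len(acfg$n_features), function(i) {
    b <- blocks[sample.int(nrow(blocks), 1L, prob = w), ]
    flen <- min(b$end - b$start + 1L, rgeom(1L, 1 / acfg$mean_len) + 1L)
    s <- b$start + sample.int(b$end - b$start + 2L - flen, 1L) - 1L
    key <- SIM_FT_KEYS[(i %% length(SIM_FT_KEYS)) + 1L]
    data.frame(protein_id = b$protein_id, start = s, end = s + flen - 1L,
               key = key, description = paste("site", key),
               qualifier = "", placed_on = b$type)
  })
  do.call(rbind, out)
}

#' Training set for the stage-2 MoRF discriminant
#'
#' Builds labelled stage-1 candidates from synthetic sequences: the
#' positive (MoRF-like) class embeds a strongly order-promoting stretch
#' (residues from W/F/Y/I) inside strongly disorder-promoting flanks,
#' the negative class a weakly order-promoting stretch (M/I/L/Y mixed
#' with V/T), which yields a shallower disorder dip. Each sequence is
#' scanned with [scan_morf_candidates()] and the first candidate's
#' feature vector is kept.
#'
#' @param n_per_class candidates per class (default 200).
#' @param seed integer seed.
#' @param ... passed to [scan_morf_candidates()].
#' @return list: `x` (feature matrix), `labels` (factor,
#'   `"non_morf"`/`"morf"` with `"morf"` the positive level).
#' @export
gen_morf_training <- function(n_per_class = 200L, seed = 7L, ...) {
  set.seed(seed)
  strong <- c("W", "F", "Y", "I")
  weak <- c("M", "I", "L", "Y", "V", "T")
  flank_pool <- c("P", "E", "K", "S", "Q")
  make_one <- function(pool) {
    for (try in 1:50) {
      sl <- sample(10:18, 1L)
      fl <- sample(15:30, 2L, replace = TRUE)
      seq <- paste(c(sample(flank_pool, fl[1], TRUE),
                     sample(pool, sl, TRUE),
                     sample(flank_pool, fl[2], TRUE)), collapse = "")
      prof <- predict_disorder(seq)
      cand <- scan_morf_candidates(prof, ...)
      if (nrow(cand) == 1L) {
        return(morf_features(cand[1, ], prof, seq))
      }
    }
    NULL
  }
  pos <- Filter(Negate(is.null),
                replicate(n_per_class, make_one(strong), simplify = FALSE))
  neg <- Filter(Negate(is.null),
                replicate(n_per_class, make_one(weak), simplify = FALSE))
  x <- rbind(do.call(rbind, neg), do.call(rbind, pos))
  labels <- factor(rep(c("non_morf", "morf"), c(length(neg), length(pos))),
                   levels = c("non_morf", "morf"))
  list(x = x, labels = labels)
}
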