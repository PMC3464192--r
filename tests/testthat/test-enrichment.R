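test_that("Fisher p-values match hypergeometric enumeration on known tables", {
  expect_equal(fisher_exact_2x2(c(5, 5, 5, 5)), 1.0)
  expect_equal(fisher_exact_2x2(c(1, 9, 9, 1)), 202 / 184756,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(c(1, 9, 9, 1)),
               oracle_fisher(1, 9, 9, 1), tolerance = 1e-12)
  expect_error(fisher_exact_2x2(c(0, 0, 0, 0)), "all-zero")
  expect_error(fisher_exact_2x2(c(1, 2, 3)), "2x2")
})

test_that("Fisher test is invariant under simultaneous row and column swaps", {
  set.seed(51)
  for (rep in 1:25) {
    t <- matrix(rpois(4, 8), 2, 2)
    if (sum(t) == 0) next
    swapped <- t[2:1, 2:1]
    expect_equal(fisher_exact_2x2(t), fisher_exact_2x2(swapped))
  }
})

test_that("Fisher test agrees with enumeration on a random sweep of small tables", {
  set.seed(52)
  for (rep in 1:200) {
    tot <- sample.int(40, 1)
    cuts <- sort(sample(0:tot, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]
    cc <- cuts[3] - cuts[2]; d <- tot - cuts[3]
    if (a + b + cc + d == 0) next
    expect_equal(fisher_exact_2x2(c(a, b, cc, d)),
                 oracle_fisher(a, b, cc, d), tolerance = 1e-9,
                 info = paste(a, b, cc, d))
  }
})

test_that("Bonferroni correction multiplies, caps, preserves order", {
  expect_equal(bonferroni(0.01), 0.01)
  expect_equal(bonferroni(c(0.01, 0.02)), c(0.02, 0.04))
  expect_equal(bonferroni(c(0.9, 0.9)), c(1, 1))
  set.seed(53)
  p <- runif(20)
  adj <- bonferroni(p)
  expect_true(all(adj >= p))
  # order-preserving up to ties introduced by the cap at 1
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(bonferroni(c(0.5, 0)), "\\(0,1\\]")
})

test_that("fold differences follow the delta method and invert under transposition", {
  fd <- fold_difference(c(670, 2686, 1125, 8665))
  expect_equal(fd$fold, (670 / 3356) / (1125 / 9790))
  expect_equal(fd$fold_se,
               fd$fold * sqrt(1 / 670 - 1 / 3356 + 1 / 1125 - 1 / 9790))
  expect_equal(fold_difference(c(10, 30, 5, 15))$fold, 1)
  inv <- fold_difference(c(1125, 8665, 670, 2686))
  expect_equal(fd$fold, 1 / inv$fold)
  expect_warning(zero <- fold_difference(c(0, 10, 5, 5)), "undefined")
  expect_true(is.na(zero$fold))
})

test_that("enrichment rows combine counts, fold, and corrected p", {
  r <- enrichment_result(c(20, 80, 10, 90), test_count = 4)
  expect_equal(r$p_adj, min(1, r$p_raw * 4))
  expect_equal(r$fold, 2)
})

test_that("composition profiles compute fractional differences with bootstrap SEs", {
  uniform <- setNames(rep(50, 20), c("A", "R", "N", "D", "C", "Q", "E",
                                     "G", "H", "I", "L", "K", "M", "F",
                                     "P", "S", "T", "W", "Y", "V"))
  same <- composition_profile(uniform, uniform, reps = 200, seed = 1)
  expect_equal(same$diff, rep(0, 20))
  only_r <- setNames(rep(0, 20), names(uniform)); only_r["R"] <- 100
  prof <- composition_profile(only_r, uniform, reps = 200, seed = 1)
  expect_equal(prof$diff[prof$res == "R"], 19)
  expect_equal(prof$diff[prof$res != "R"], rep(-1, 19))
  # bit-reproducible under a fixed seed
  again <- composition_profile(only_r, uniform, reps = 200, seed = 1)
  expect_identical(prof, again)
  expect_error(composition_profile(uniform, only_r, reps = 200),
               "background frequency zero")
})

test_that("bootstrap SE shrinks roughly as 1/sqrt(n)", {
  comp <- c(rep(40, 10), rep(60, 10))
  names(comp) <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  small <- composition_profile(comp, comp, reps = 3000, seed = 2)
  big <- composition_profile(comp * 4, comp, reps = 3000, seed = 2)
  ratio <- mean(small$se / big$se)
  expect_equal(ratio, 2, tolerance = 0.15)
})

test_that("feature normalization strips qualifiers, prefixes, rare and disease features", {
  ann <- data.frame(
    protein_id = "p1", start = 1L, end = 5L,
    key = c(rep("REGION", 6), "REGION", "Disease", rep("MOTIF", 4)),
    description = c(rep("Required for DNA binding", 6),
                    "zinc finger", "syndrome X",
                    rep("Involved in signaling", 4)),
    qualifier = c(rep("", 6), "By similarity", "", rep("", 4)),
    dataset = "DM")
  norm <- normalize_ft(ann, min_count = 5)
  expect_true(all(norm$level2 == "REGION DNA binding"))
  expect_equal(nrow(norm), 6L)  # qualifier row, disease row, rare rows gone
  # prefix stripping is case-insensitive and collapses whitespace
  expect_equal(idrmut:::strip_prefixes("required for  DNA binding",
                                       idrmut:::FT_PREFIXES),
               "DNA binding")
  expect_equal(idrmut:::strip_prefixes("For X", idrmut:::FT_PREFIXES), "X")
})

test_that("interval overlap uses 1-based inclusive bounds", {
  iv <- data.frame(protein_id = "p1", start = 3L, end = 7L)
  calls <- data.frame(protein_id = "p1", position = c(5L, 8L, 3L, 7L, 2L),
                      dataset = "DM")
  res <- interval_overlap(calls, iv)
  expect_equal(res$counts$overlapping, 3L)
  expect_equal(res$counts$n, 5L)
})

test_that("interval overlap stratifies and tests across datasets", {
  iv <- data.frame(protein_id = "p1", start = 1L, end = 10L)
  calls <- data.frame(protein_id = "p1",
                      position = rep(c(5L, 50L), c(30, 30)),
                      dataset = rep(c("DM", "Poly"), 30),
                      class = factor(rep("D->O", 60)))
  res <- interval_overlap(calls, iv)
  expect_equal(nrow(res$counts), 2L)
  expect_equal(nrow(res$tests), 1L)
  expect_true(res$tests$p_raw <= 1)
})

test_that("planted annotation enrichment is recovered within 3 SE", {
  cfg <- sim_config(n_proteins = 40L, morf_density = 0,
                    datasets = list(DM = list(n = 1200L, p_do = 0,
                                              p_od = 0)),
                    annotation = list(n_features = 120L, odds = 3,
                                      mean_len = 8), seed = 505L)
  sim <- gen_proteins(cfg)
  mut <- gen_mutations(sim$proteins, sim$labels, cfg)
  ann <- gen_annotations(sim$proteins, sim$labels, cfg)
  # stratify mutations by true block label at the mutated residue
  lab <- mapply(function(id, pos) sim$labels[[id]][pos],
                mut$mutations$protein_id, mut$mutations$position)
  strat <- mut$mutations
  strat$stratum <- ifelse(lab == "D", "IDR", "OR")
  hit <- idrmut:::overlaps_any(strat, ann)
  tab <- c(sum(hit & strat$stratum == "IDR"),
           sum(!hit & strat$stratum == "IDR"),
           sum(hit & strat$stratum == "OR"),
           sum(!hit & strat$stratum == "OR"))
  fd <- fold_difference(tab)
  expect_lte(abs(fd$fold - cfg$annotation$odds), 3 * fd$fold_se)
})

test_that("ft_enrichment tests per feature with a shared Bonferroni family", {
  ann <- data.frame(protein_id = "p1",
                    start = c(1L, 30L), end = c(10L, 40L),
                    key = c("DNA_BIND", "TRANSMEM"),
                    description = "x", qualifier = "",
                    level1 = c("DNA_BIND", "TRANSMEM"),
                    level2 = c("DNA_BIND x", "TRANSMEM x"))
  m <- data.frame(protein_id = "p1",
                  position = c(rep(5L, 20), rep(35L, 5), rep(60L, 20),
                               rep(5L, 4), rep(35L, 16), rep(60L, 20)),
                  stratum = rep(c("IDR", "OR"), c(45, 40)))
  res <- ft_enrichment(ann, m, "IDR", "OR", level = "level1")
  expect_equal(nrow(res), 2L)
  expect_equal(unique(res$test_count), 2L)
  expect_equal(res$p_adj, pmin(1, res$p_raw * 2))
  expect_equal(res$fold, sort(res$fold, decreasing = TRUE))
  # a feature hit in neither stratum is excluded
  ann2 <- rbind(ann, transform(ann[1, ], start = 900L, end = 950L,
                               level1 = "FAR", level2 = "FAR x"))
  res2 <- ft_enrichment(ann2, m, "IDR", "OR", level = "level1")
  expect_equal(nrow(res2), 2L)
})

test_that("stratified external calls report fractions that sum to one", {
  set.seed(54)
  n <- 300
  calls <- data.frame(protein_id = "p", position = 1L,
                      dataset = "DM",
                      wt_ps = runif(n), mut_ps = runif(n))
  calls$class <- classify_transition(calls$wt_ps, calls$mut_ps)
  calls$call <- sample(c("damaging", "tolerated", "unknown"), n,
                       replace = TRUE, prob = c(0.5, 0.4, 0.1))
  res <- stratified_calls(calls)
  expect_true(all(abs(rowSums(res$fractions) - 1) < 1e-12))
  expect_true(all(res$tests$p_raw > 0 & res$tests$p_raw <= 1))
  same <- calls; same$call <- "damaging"
  res2 <- stratified_calls(same)
  expect_true(all(res2$fractions[, "damaging"] == 1))
  expect_equal(res2$tests$p_raw, 1)
})

test_that("a planted IDR/OR difference in external calls is detected", {
  set.seed(55)
  n <- 600
  wt_ps <- runif(n)
  damaging <- rbinom(n, 1, ifelse(wt_ps >= 0.5, 0.45, 0.75)) == 1
  calls <- data.frame(protein_id = "p", position = 1L, dataset = "DM",
                      wt_ps = wt_ps, mut_ps = runif(n),
                      call = ifelse(damaging, "damaging", "tolerated"))
  calls$class <- classify_transition(calls$wt_ps, calls$mut_ps)
  res <- stratified_calls(calls)
  dmg <- res$tests[grepl("damaging", res$tests$label), ]
  expect_lt(dmg$p_raw, 0.01)
  expect_lt(dmg$fold, 1)  # fewer damaging calls in IDR
})
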