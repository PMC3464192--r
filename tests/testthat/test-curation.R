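test_that("identical sequences align at 100% identity with no gaps", {
  al <- global_align("MKTAYIAK", "MKTAYIAK")
  expect_equal(al$identity_pct, 100)
  expect_equal(al$aligned_a, "MKTAYIAK")
  expect_equal(al$aligned_b, "MKTAYIAK")
})

test_that("a single substitution gives 8/9 identity", {
  al <- global_align("ACDEFGHIK", "ACDEFGHIR")
  expect_equal(al$identity_pct, 100 * 8 / 9, tolerance = 1e-9)
  expect_equal(nchar(al$aligned_a), 9L)
})

test_that("alignment scores equal brute-force enumeration for short pairs", {
  set.seed(41)
  mat <- blosum85()
  for (rep in 1:40) {
    la <- sample.int(6, 1); lb <- sample.int(6, 1)
    a <- paste(sample(rownames(mat), la, replace = TRUE), collapse = "")
    b <- paste(sample(rownames(mat), lb, replace = TRUE), collapse = "")
    al <- global_align(a, b)
    expect_equal(al$score, oracle_align_score(a, b, mat, -11, -1),
                 info = paste(a, b))
    # de-gapped aligned strings reproduce the inputs
    expect_equal(gsub("-", "", al$aligned_a), a)
    expect_equal(gsub("-", "", al$aligned_b), b)
  }
})

test_that("alignment score and identity are symmetric in argument order", {
  set.seed(42)
  for (rep in 1:10) {
    a <- paste(sample(rownames(blosum85()), 15, replace = TRUE), collapse = "")
    b <- paste(sample(rownames(blosum85()), 12, replace = TRUE), collapse = "")
    ab <- global_align(a, b)
    ba <- global_align(b, a)
    expect_equal(ab$score, ba$score)
    expect_equal(ab$identity_pct, ba$identity_pct)
  }
  expect_error(global_align("", "AK"), "empty")
})

test_that("aligned identity drops double-gap columns", {
  expect_equal(aligned_identity("AC-D", "AC-E"), 100 * 2 / 3)
  expect_equal(aligned_identity("A-CD", "AGCD"), 75)
})

test_that("single-linkage clustering is transitive and matches a union-find oracle", {
  base <- paste(rep(c("M", "K", "T", "A", "Y", "I", "E", "R", "L", "V"), 4),
                collapse = "")
  mutate_seq <- function(s, k, offset = 0) {
    ch <- strsplit(s, "")[[1]]
    idx <- seq(1 + offset, by = 2, length.out = k)
    repl <- c("G", "S", "N", "D", "Q", "H", "W", "F", "P", "C")
    ch[idx] <- rep(repl, length.out = k)
    paste(ch, collapse = "")
  }
  prot <- c(A = base,
            B = mutate_seq(base, 16),          # ~60% identical to A
            C = mutate_seq(base, 16, offset = 7),
            D = paste(rev(strsplit(strrep("PW", 20), "")[[1]]), collapse = ""))
  cl <- cluster_redundant(prot, identity_threshold = 40, seed = 5)
  idm <- cl$identity
  # union-find oracle over the pairwise identity graph
  parent <- setNames(names(prot), names(prot))
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in names(prot)) for (j in names(prot)) {
    if (i < j && idm[i, j] >= 40) parent[[find(i)]] <- find(j)
  }
  roots <- vapply(names(prot), find, character(1))
  expect_equal(length(unique(roots)), length(cl$representatives))
  same_oracle <- outer(roots, roots, "==")
  same_pkg <- outer(cl$cluster, cl$cluster, "==")
  expect_equal(unname(same_pkg), unname(same_oracle))
  # every representative is a member of its cluster
  expect_true(all(cl$representatives %in% names(prot)))
})

test_that("two identical proteins form one cluster; dissimilar ones stay singletons", {
  prot <- c(x = "MKTAYIAKQRQISFVK", y = "MKTAYIAKQRQISFVK",
            z = "PPPPPPPPWWWWWWWW")
  cl <- cluster_redundant(prot, identity_threshold = 40, seed = 1)
  expect_equal(cl$cluster[["x"]], cl$cluster[["y"]])
  expect_false(cl$cluster[["x"]] == cl$cluster[["z"]])
  all_diff <- cluster_redundant(c(a = "MKTAYIAKQRQISFVK",
                                  b = "PPPPPPPPWWWWWWWW"),
                                identity_threshold = 40, seed = 1)
  expect_equal(length(all_diff$representatives), 2L)
})

test_that("the cluster partition ignores input order and the seed; representatives use the seed", {
  prot <- c(x = "MKTAYIAKQRQISFVK", y = "MKTAYIAKQRQISFVK",
            z = "MKTAYIAKQRQISFVR", w = "PPPPPPPPWWWWWWWW")
  cl1 <- cluster_redundant(prot, seed = 1)
  cl2 <- cluster_redundant(prot[c(3, 1, 4, 2)], seed = 1)
  expect_equal(cl1$cluster, cl2$cluster[names(cl1$cluster)])
  cl3 <- cluster_redundant(prot, seed = 99)
  expect_equal(outer(cl1$cluster, cl1$cluster, "=="),
               outer(cl3$cluster, cl3$cluster, "=="))
  # filtering keeps only representative-protein mutations and counts the rest
  mut <- data.frame(protein_id = c("x", "y", "w"), position = 1L,
                    wt_aa = "M", mut_aa = "V", dataset = "DM")
  mut$wt_aa[3] <- "P"
  kept <- apply_cluster_filter(mut, cl1)
  expect_equal(nrow(kept) + attr(kept, "discarded"), 3L)
  expect_true(all(kept$protein_id %in% cl1$representatives))
})

test_that("outlier flagging supports top-k and count thresholds", {
  mut <- data.frame(protein_id = rep(c("a", "b", "c", "d"),
                                     c(100, 5, 4, 3)),
                    position = 1L, wt_aa = "M", mut_aa = "V",
                    dataset = "DM")
  top <- flag_outliers(mut, "top_k", 1)
  expect_equal(top$flagged, "a")
  expect_equal(top$removed_fraction, 100 / 112)
  ge <- flag_outliers(mut, "count_ge", 5)
  expect_equal(sort(ge$flagged), c("a", "b"))
  expect_equal(flag_outliers(mut, "count_ge", 1000)$flagged, character(0))
  expect_error(flag_outliers(mut, "top_k", 10), "exceeds")
})

test_that("NES extraction applies the identity cutoff, coordinates, and filters", {
  human <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"  # 33 residues
  mutate_at <- function(s, pos, aa) { substr(s, pos, pos) <- aa; s }
  orth_close <- mutate_at(human, 10, "K")      # 1 diff -> ~97% identity
  orth_far <- human
  for (p in seq(1, 21, by = 2)) orth_far <- mutate_at(orth_far, p, "G")
  nes <- extract_nes("p1", human,
                     list(sp1 = orth_close, sp2 = orth_far),
                     min_identity = 95)
  expect_equal(nrow(nes), 1L)
  expect_equal(nes$position, 10L)
  expect_equal(nes$wt_aa, "R")
  expect_equal(nes$mut_aa, "K")
  # the same record annotated as a disease mutation is filtered out
  dm <- data.frame(protein_id = "p1", position = 10L, wt_aa = "R",
                   mut_aa = "K", dataset = "DM")
  expect_equal(nrow(extract_nes("p1", human, list(sp1 = orth_close),
                                disease_mutations = dm)), 0L)
})

test_that("NES respects gaps, dedupes across orthologs, and can keep multiplicity", {
  human <- "MKTAYIAKQR-QISFVKSHFSRQLEERLGLIEVQA"  # gapped human column 11
  orth <- "MKTAYIAKQRWKISFVKSHFSRQLEERLGLIEVQA"   # insertion + 1 diff
  nes <- extract_nes("p1", human, list(sp1 = orth, sp2 = orth),
                     min_identity = 90)
  # the column where human is gapped has no human coordinate
  expect_equal(nes$position, 11L)
  expect_equal(nes$wt_aa, "Q")
  expect_equal(nrow(nes), 1L)
  multi <- extract_nes("p1", human, list(sp1 = orth, sp2 = orth),
                       min_identity = 90, keep_multiplicity = TRUE)
  expect_equal(nrow(multi), 2L)
  expect_error(extract_nes("p1", human, list(sp1 = "MK")), "mismatch")
})
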