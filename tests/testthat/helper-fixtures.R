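# small in-code fixtures shared across test files

fixture_fasta <- function(entries, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "seqs.fasta")
  writeLines(unlist(lapply(names(entries), function(id) {
    c(paste0(">", id), entries[[id]])
  })), path)
  path
}

fixture_tsv <- function(df, name = "table.tsv",
                        dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

new_profile_for_test <- function(id, scores) {
  idrmut:::new_disorder_profile(id, scores, "external")
}

# three tiny proteins with contrasting disorder architecture
tiny_proteins <- function() {
  c(p1 = paste0(strrep("P", 30), strrep("W", 15), strrep("E", 30)),
    p2 = strrep("K", 40),
    p3 = paste0(strrep("I", 25), strrep("S", 25)))
}

# independent run-length oracle for the stage-1 MoRF scan
oracle_morf_scan <- function(scores, min_len, max_len, min_flank) {
  ordered <- scores < 0.5
  n <- length(scores)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (!ordered[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && ordered[j + 1L]) j <- j + 1L
    len <- j - i + 1L
    left <- 0L; k <- i - 1L
    while (k >= 1L && !ordered[k]) { left <- left + 1L; k <- k - 1L }
    right <- 0L; k <- j + 1L
    while (k <= n && !ordered[k]) { right <- right + 1L; k <- k + 1L }
    if (len >= min_len && len <= max_len &&
        left >= min_flank && right >= min_flank) {
      out[[length(out) + 1L]] <- c(start = i, end = j)
    }
    i <- j + 1L
  }
  out
}

# exhaustive two-sided Fisher p by hypergeometric enumeration
oracle_fisher <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force global alignment score by recursive enumeration; affine
# gap of length L costs open + (L - 1) * ext
oracle_align_score <- function(a, b, mat, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= length(ca)) {
      pen <- if (state == "X") ext else open
      best <- max(best, pen + rec(i + 1L, j, "X"))
    }
    if (j <= length(cb)) {
      pen <- if (state == "Y") ext else open
      best <- max(best, pen + rec(i, j + 1L, "Y"))
    }
    best
  }
  rec(1L, 1L, "M")
}
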