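#' Optimal global alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh dynamic programming over a substitution
#' matrix (default BLOSUM85), with a gap of length L costing
#' `gap_open + (L - 1) * gap_extend`. Tie-breaking in the traceback is
#' deterministic (diagonal over up over left), so the same pair always
#' yields the same alignment. Percent identity is computed over all
#' alignment columns (there are no double-gap columns in a pairwise
#' alignment) or, optionally, over the shorter sequence length.
#'
#' @param seq_a,seq_b protein sequences (non-empty).
#' @param matrix substitution matrix with residue dimnames.
#' @param gap_open,gap_extend negative gap penalties (defaults -11, -1).
#' @param identity_denominator `"columns"` (default) or `"shorter"`.
#' @return list of class `alignment_result`: `aligned_a`, `aligned_b`
#'   (gapped strings), `score`, `identity_pct`.
#' @export
global_align <- function(seq_a, seq_b, matrix = blosum85(),
                         gap_open = -11, gap_extend = -1,
                         identity_denominator = c("columns", "shorter")) {
  identity_denominator <- match.arg(identity_denominator)
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) stop("empty sequence")
  if (gap_open > 0 || gap_extend > 0) stop("gap penalties must be <= 0")
  alpha <- rownames(matrix)
  ca <- strsplit(toupper(seq_a), "")[[1]]
  cb <- strsplit(toupper(seq_b), "")[[1]]
  ia <- match(ca, alpha) - 1L
  ib <- match(cb, alpha) - 1L
  if (anyNA(ia) || anyNA(ib)) {
    stop("sequence contains residues absent from the substitution matrix")
  }
  res <- .align_affine(ia, ib, matrix, gap_open, gap_extend)
  ops <- strsplit(res$ops, "")[[1]]
  aligned_a <- aligned_b <- character(length(ops))
  i <- j <- 0L
  for (k in seq_along(ops)) {
    if (ops[k] != "Y") { i <- i + 1L; aligned_a[k] <- ca[i] }
    else aligned_a[k] <- "-"
    if (ops[k] != "X") { j <- j + 1L; aligned_b[k] <- cb[j] }
    else aligned_b[k] <- "-"
  }
  matches <- sum(aligned_a == aligned_b & aligned_a != "-")
  denom <- if (identity_denominator == "columns") length(ops)
           else min(length(ca), length(cb))
  structure(list(aligned_a = paste(aligned_a, collapse = ""),
                 aligned_b = paste(aligned_b, collapse = ""),
                 score = res$score,
                 identity_pct = 100 * matches / denom),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment> score =", x$score,
      sprintf("identity = %.1f%%\n", x$identity_pct))
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Percent identity of an aligned (gapped) sequence pair
#'
#' For pairs projected out of a multiple alignment: columns where both
#' members are gaps are dropped first, then identity is the fraction of
#' remaining columns with identical residues.
#'
#' @param aligned_a,aligned_b equal-length gapped strings.
#' @return identity percentage in \[0, 100\].
#' @export
aligned_identity <- function(aligned_a, aligned_b) {
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  if (length(ca) != length(cb)) stop("aligned lengths differ")
  keep <- !(ca == "-" & cb == "-")
  ca <- ca[keep]; cb <- cb[keep]
  100 * sum(ca == cb & ca != "-") / length(ca)
}

#' Cluster redundant proteins by pairwise identity
#'
#' All-against-all global alignment; proteins whose pairwise identity
#' meets the threshold are joined, and clusters are the single-linkage
#' connected components of that graph (so A-B and B-C at threshold pulls
#' A, B, C into one cluster even when A-C is below it). One
#' representative is drawn uniformly at random per cluster using the
#' seed; the partition itself does not depend on the seed.
#'
#' @param proteins named character vector of sequences.
#' @param identity_threshold percent identity in (0, 100\]; default 40.
#' @param seed integer seed for representative selection.
#' @param ... passed to [global_align()].
#' @return list of class `cluster_assignment`: `cluster` (named integer
#'   vector protein -> cluster id), `representatives` (one protein id per
#'   cluster), `identity` (pairwise identity matrix), `seed`.
#' @export
cluster_redundant <- function(proteins, identity_threshold = 40,
                              seed = 1L, ...) {
  if (length(proteins) == 0L) stop("no proteins")
  if (identity_threshold <= 0 || identity_threshold > 100) {
    stop("identity_threshold must be in (0, 100]")
  }
  ids <- sort(names(proteins))
  n <- length(ids)
  idm <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        al <- global_align(proteins[[ids[i]]], proteins[[ids[j]]], ...)
        idm[i, j] <- idm[j, i] <- al$identity_pct
      }
    }
  }
  adj <- idm >= identity_threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  cluster <- setNames(as.integer(comp), ids)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  reps <- vapply(sort(unique(cluster)), function(k) {
    members <- sort(names(cluster)[cluster == k])
    members[sample.int(length(members), 1L)]
  }, character(1))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  structure(list(cluster = cluster, representatives = unname(reps),
                 identity = idm, seed = seed),
            class = "cluster_assignment")
}

#' Drop mutations on non-representative proteins
#'
#' @param mutations validated mutation data.frame.
#' @param assignment a `cluster_assignment`.
#' @return kept mutations, with the number discarded in the
#'   `"discarded"` attribute.
#' @export
apply_cluster_filter <- function(mutations, assignment) {
  keep <- mutations$protein_id %in% assignment$representatives
  out <- mutations[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discarded") <- sum(!keep)
  out
}

#' Flag proteins with an unusually high mutation burden
#'
#' Supports two rules: `"top_k"` flags the k proteins with the most
#' mutations (ties broken by protein id for reproducibility), and
#' `"count_ge"` flags every protein carrying at least `k_or_threshold`
#' mutations. Mutations on flagged proteins are meant to be removed
#' downstream; the removed fraction is reported.
#'
#' @param mutations mutation data.frame.
#' @param method `"top_k"` or `"count_ge"`.
#' @param k_or_threshold k for `"top_k"`, the count threshold for
#'   `"count_ge"`.
#' @return list: `flagged` (protein ids), `removed_fraction` (fraction of
#'   mutations on flagged proteins), `counts` (per-protein mutation
#'   counts, decreasing).
#' @export
flag_outliers <- function(mutations, method = c("top_k", "count_ge"),
                          k_or_threshold) {
  method <- match.arg(method)
  counts <- table(mutations$protein_id)
  counts <- counts[order(-as.integer(counts), names(counts))]
  flagged <- if (method == "top_k") {
    if (k_or_threshold > length(counts)) {
      stop("k exceeds the number of proteins")
    }
    names(counts)[seq_len(k_or_threshold)]
  } else {
    names(counts)[as.integer(counts) >= k_or_threshold]
  }
  removed <- sum(mutations$protein_id %in% flagged)
  list(flagged = flagged,
       removed_fraction = removed / nrow(mutations),
       counts = counts)
}

#' Neutral evolutionary substitutions from ortholog alignments
#'
#' For every ortholog aligned to the human protein at or above
#' `min_identity` percent identity, each alignment column where the two
#' residues differ, neither is a gap, and both are canonical yields a
#' pseudo-mutation human -> ortholog residue at the human 1-based
#' coordinate (columns where the human sequence is gapped have no human
#' coordinate and are skipped). Records identical to an annotated
#' disease mutation (same protein, position, wild-type and mutant
#' residue) are filtered out. Duplicates arising from several orthologs
#' carrying the same difference collapse to one record by default; with
#' `keep_multiplicity = TRUE` each ortholog contributes its own record.
#'
#' @param protein_id identifier of the human protein.
#' @param human_aligned gapped human sequence, identical across pairs.
#' @param ortholog_alignments named list of gapped ortholog sequences,
#'   each the same aligned length as `human_aligned`, or a list of
#'   `alignment_result` objects with the human sequence as `aligned_a`.
#' @param min_identity minimum percent identity (default 95).
#' @param disease_mutations optional mutation data.frame used to filter
#'   out annotated disease substitutions.
#' @param keep_multiplicity retain one record per contributing ortholog.
#' @param dataset label stamped on the output records (default "NES").
#' @return mutation data.frame of pseudo-substitutions.
#' @export
extract_nes <- function(protein_id, human_aligned, ortholog_alignments,
                        min_identity = 95, disease_mutations = NULL,
                        keep_multiplicity = FALSE, dataset = "NES") {
  recs <- list()
  for (nm in names(ortholog_alignments)) {
    o <- ortholog_alignments[[nm]]
    if (inherits(o, "alignment_result")) {
      ha <- o$aligned_a; oa <- o$aligned_b
    } else {
      ha <- human_aligned; oa <- o
    }
    ch <- strsplit(ha, "")[[1]]
    co <- strsplit(oa, "")[[1]]
    if (length(ch) != length(co)) {
      stop("alignment length mismatch for ortholog ", nm)
    }
    keep <- !(ch == "-" & co == "-")
    ch <- ch[keep]; co <- co[keep]
    if (aligned_identity(paste(ch, collapse = ""),
                         paste(co, collapse = "")) < min_identity) next
    hpos <- cumsum(ch != "-")
    diff <- ch != co & ch != "-" & co != "-" & ch %in% AA20 & co %in% AA20
    if (!any(diff)) next
    recs[[nm]] <- data.frame(protein_id = protein_id,
                             position = hpos[diff],
                             wt_aa = ch[diff], mut_aa = co[diff],
                             dataset = dataset, ortholog = nm)
  }
  if (length(recs) == 0L) {
    return(data.frame(protein_id = character(), position = integer(),
                      wt_aa = character(), mut_aa = character(),
                      dataset = character(), ortholog = character()))
  }
  out <- do.call(rbind, recs)
  if (!is.null(disease_mutations) && nrow(disease_mutations) > 0L) {
    key <- function(d) paste(d$protein_id, d$position, d$wt_aa, d$mut_aa)
    out <- out[!key(out) %in% key(disease_mutations), , drop = FALSE]
  }
  if (!keep_multiplicity) {
    out <- out[!duplicated(paste(out$protein_id, out$position,
                                 out$wt_aa, out$mut_aa)), , drop = FALSE]
    out$ortholog <- NULL
  }
  out <- out[order(out$position, out$mut_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}
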