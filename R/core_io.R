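#' Read protein sequences from a FASTA file
#'
#' Identifiers are taken from the header line up to the first whitespace;
#' sequences are upper-cased. Residues outside the 20-letter canonical
#' alphabet are handled according to `policy`: `"strict"` (default) raises
#' an error, `"mask"` replaces them with `"X"`, which the built-in
#' predictor scores at the propensity-scale mean.
#'
#' @param path FASTA file.
#' @param policy `"strict"` or `"mask"`.
#' @return named character vector of sequences (names are protein ids).
#' @export
read_fasta <- function(path, policy = c("strict", "mask")) {
  policy <- match.arg(policy)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  sanitize_sequences(seqs, policy)
}

sanitize_sequences <- function(seqs, policy = c("strict", "mask")) {
  policy <- match.arg(policy)
  bad <- vapply(seqs, function(s) {
    any(!strsplit(s, "")[[1]] %in% AA20)
  }, logical(1))
  if (any(nchar(seqs) == 0L)) stop("zero-length sequence")
  if (any(bad)) {
    if (policy == "strict") {
      stop("non-canonical residues in: ",
           paste(names(seqs)[bad], collapse = ", "),
           " (use policy = \"mask\" to accept)")
    }
    seqs[bad] <- vapply(seqs[bad], function(s) {
      ch <- strsplit(s, "")[[1]]
      ch[!ch %in% AA20] <- "X"
      paste(ch, collapse = "")
    }, character(1))
  }
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read and validate a mutation table
#'
#' Expects a tab-delimited file with header columns `protein_id`,
#' `position` (1-based), `wt_aa`, `mut_aa` and optionally `dataset`.
#' Rows whose annotated wild-type residue does not match the sequence are
#' rejected (not an error) and reported via the `"rejected"` attribute and
#' a message; unknown proteins, out-of-range positions and `wt == mut`
#' rows abort.
#'
#' @param path TSV file (`#` lines are comments).
#' @param proteins named character vector of sequences.
#' @return data.frame of accepted mutations with attribute `"rejected"`
#'   holding the rejected rows (with a `reason` column).
#' @export
read_mutations <- function(path, proteins) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "wt_aa", "mut_aa")
  if (!all(need %in% names(tab))) {
    stop("mutation table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(tab$dataset)) tab$dataset <- "user"
  validate_mutations(tab, proteins)
}

#' Validate mutation records against their proteins
#'
#' @param mutations data.frame with columns `protein_id`, `position`,
#'   `wt_aa`, `mut_aa` and optionally `dataset`.
#' @param proteins named character vector of sequences.
#' @return the accepted rows, with rejected wild-type-mismatch rows in the
#'   `"rejected"` attribute.
#' @export
validate_mutations <- function(mutations, proteins) {
  m <- mutations
  m$position <- as.integer(m$position)
  m$wt_aa <- toupper(m$wt_aa)
  m$mut_aa <- toupper(m$mut_aa)
  unknown <- !m$protein_id %in% names(proteins)
  if (any(unknown)) {
    stop("unknown protein ids: ",
         paste(unique(m$protein_id[unknown]), collapse = ", "))
  }
  len <- nchar(proteins)[m$protein_id]
  if (any(m$position < 1L | m$position > len)) {
    stop("mutation positions out of range for: ",
         paste(unique(m$protein_id[m$position < 1L | m$position > len]),
               collapse = ", "))
  }
  if (any(m$wt_aa == m$mut_aa)) {
    stop("records with wt_aa == mut_aa are not mutations")
  }
  actual <- substr(proteins[m$protein_id], m$position, m$position)
  mismatch <- actual != m$wt_aa
  rejected <- m[mismatch, , drop = FALSE]
  if (nrow(rejected) > 0L) {
    rejected$reason <- "wt_mismatch"
    message(nrow(rejected), " mutation record(s) rejected: annotated ",
            "wild-type residue does not match the sequence")
  }
  out <- m[!mismatch, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a mutation table
#'
#' @param mutations data.frame as returned by [read_mutations()].
#' @param path output TSV.
#' @export
write_mutations <- function(mutations, path) {
  write.table(mutations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-residue score or secondary-structure tracks
#'
#' Dense per-residue tracks from an external predictor, one row per
#' residue: columns `protein_id`, `position` (1-based), `score`, and for
#' secondary-structure tracks additionally `state` (H/E/L) and
#' `reliability` (integer 0-9). Positions must cover `1..L` without gaps;
#' missing positions are an error — no imputation is done. Disorder
#' scores must lie in \[0, 1\].
#'
#' @param path TSV file.
#' @return named list, one element per protein: a `disorder_profile` for
#'   score-only files, or a list with `state` and `reliability` vectors
#'   for secondary-structure files.
#' @export
read_score_track <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "score")
  if (!all(need %in% names(tab))) {
    stop("score track must have columns: ", paste(need, collapse = ", "))
  }
  has_state <- "state" %in% names(tab)
  out <- lapply(split(tab, tab$protein_id), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    if (!identical(as.integer(d$position), seq_len(nrow(d)))) {
      stop("track for ", d$protein_id[1],
           " has missing or duplicated positions (dense 1..L required)")
    }
    if (has_state) {
      if (!all(d$state %in% c("H", "E", "L"))) {
        stop("unknown secondary-structure state in track for ",
             d$protein_id[1])
      }
      list(protein_id = d$protein_id[1], state = d$state,
           reliability = as.integer(d$reliability), score = d$score)
    } else {
      if (any(d$score < 0 | d$score > 1)) {
        stop("disorder scores outside [0,1] for ", d$protein_id[1])
      }
      new_disorder_profile(d$protein_id[1], d$score, "external")
    }
  })
  out[unique(tab$protein_id)]
}

#' Read region/residue feature annotations
#'
#' Tab-delimited emulation of UniProt feature-table lines: columns
#' `protein_id`, `start`, `end` (1-based inclusive), `key`,
#' `description`, optional `qualifier` (`Potential`, `Probable`,
#' `By similarity` or empty) and optional `dataset`.
#'
#' @param path TSV file.
#' @param proteins optional named sequence vector; when given, intervals
#'   are checked against sequence lengths.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path, proteins = NULL) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("protein_id", "start", "end", "key", "description")
  if (!all(need %in% names(tab))) {
    stop("annotation table must have columns: ",
         paste(need, collapse = ", "))
  }
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  if (is.null(tab$qualifier)) tab$qualifier <- ""
  if (any(tab$start > tab$end)) stop("annotation with start > end")
  if (any(tab$start < 1L)) stop("annotation start below 1")
  if (!is.null(proteins)) {
    len <- nchar(proteins)[tab$protein_id]
    if (anyNA(len)) stop("annotation for unknown protein")
    if (any(tab$end > len)) stop("annotation extends past sequence end")
  }
  tab
}

#' Read an aligned FASTA file
#'
#' Sequences may contain the gap symbol `-`; all aligned lengths must be
#' equal. Pairs of rows are later projected out of the multiple alignment
#' by dropping columns where both members are gaps.
#'
#' @param path aligned FASTA file.
#' @return named character vector of aligned (gapped) sequences.
#' @export
read_aligned_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (length(unique(nchar(seqs))) != 1L) {
    stop("aligned sequences must all have the same length")
  }
  seqs
}

new_disorder_profile <- function(protein_id, scores, predictor) {
  stopifnot(all(scores >= 0 & scores <= 1))
  structure(list(protein_id = protein_id, scores = as.numeric(scores),
                 predictor = predictor),
            class = "disorder_profile")
}

#' @export
print.disorder_profile <- function(x, ...) {
  cat("<disorder_profile> ", x$protein_id, ": ", length(x$scores),
      " residues, predictor = ", x$predictor,
      sprintf(", disordered fraction = %.3f", disorder_content(x)),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.disorder_profile <- function(x) length(x$scores)
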