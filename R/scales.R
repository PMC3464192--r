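#' Built-in residue scales and substitution matrices
#'
#' The package ships three small lookup tables as plain-text files under
#' `inst/extdata/`:
#' * `top_idp.tsv` — the TOP-IDP disorder propensity scale (Campen et al.
#'   2008). Positive values are disorder-promoting (proline highest),
#'   negative values order-promoting (tryptophan lowest). This is the
#'   default scale of the built-in disorder predictor.
#' * `vihinen_flexibility.tsv` — normalized B-factor flexibility indices
#'   (Vihinen et al. 1994), used only to order residues in substitution
#'   matrix output.
#' * `blosum85.tsv` — the BLOSUM85 log-odds substitution matrix used for
#'   pairwise global alignment during dataset curation.
#'
#' @param name scale name, `"top_idp"` or `"vihinen"`.
#' @return `propensity_scale()` returns a named numeric vector over the 20
#'   canonical residues; `blosum85()` returns a 20x20 integer matrix with
#'   residue dimnames.
#' @examples
#' sc <- propensity_scale()
#' sc["P"] > sc["W"]  # proline disorder-promoting, tryptophan order-promoting
#' @export
propensity_scale <- function(name = c("top_idp", "vihinen")) {
  name <- match.arg(name)
  file <- switch(name,
    top_idp = "top_idp.tsv",
    vihinen = "vihinen_flexibility.tsv")
  path <- system.file("extdata", file, package = "idrmut", mustWork = TRUE)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  sc <- setNames(tab[[2]], tab[[1]])
  if (!setequal(names(sc), AA20) || length(sc) != 20L) {
    stop("scale file must cover exactly the 20 canonical residues")
  }
  sc[AA20]
}

#' Read a user-supplied propensity scale
#'
#' Two-column TSV (`res`, value) with exactly one finite value per
#' canonical residue; `#` lines are comments.
#'
#' @param path file path.
#' @return named numeric vector over the 20 canonical residues.
#' @export
read_scale <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  sc <- setNames(as.numeric(tab[[2]]), toupper(tab[[1]]))
  if (!setequal(names(sc), AA20)) {
    stop("scale must have exactly one entry per canonical residue")
  }
  if (any(!is.finite(sc))) stop("scale values must be finite")
  sc[AA20]
}

#' @rdname propensity_scale
#' @export
blosum85 <- function() {
  path <- system.file("extdata", "blosum85.tsv", package = "idrmut",
                      mustWork = TRUE)
  tab <- read.delim(path, comment.char = "#", row.names = 1,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  colnames(m) <- rownames(m)
  storage.mode(m) <- "integer"
  m[AA20, AA20]
}

#' Residue ordering for substitution-matrix display
#'
#' @param ordering `"vihinen"` (rigid to flexible, mirrors the customary
#'   heat-map layout) or `"alphabetical"`.
#' @return character vector of the 20 residues in display order.
#' @export
residue_order <- function(ordering = c("vihinen", "alphabetical")) {
  ordering <- match.arg(ordering)
  if (ordering == "alphabetical") return(sort(AA20))
  flex <- propensity_scale("vihinen")
  names(sort(flex))
}
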