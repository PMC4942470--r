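#' Define a marker locus
#'
#' A locus is described by its allele labels, optionally their population
#' frequencies, and a designated reference allele.  The reference allele is
#' the allele whose coding variables are omitted from the reduced (full-rank)
#' model parameterizations; internally the allele list is reordered so that
#' the reference allele comes last.
#'
#' @param name character scalar, locus label (used in column names).
#' @param alleles character vector of at least two distinct allele labels.
#' @param freqs optional numeric vector of allele frequencies, one per
#'   allele (in the order of `alleles`), each in (0, 1) and summing to 1.
#' @param ref_allele optional reference allele label.  Defaults to the most
#'   frequent allele when `freqs` is supplied (estimation accuracy is best
#'   with a common reference), otherwise to the last allele listed.
#' @return An object of class `"locus"` with elements `name`, `alleles`
#'   (reference allele last), `freqs` (reordered accordingly, or `NULL`) and
#'   `m` (number of alleles).
#' @examples
#' locus("L1", c("1", "0"), freqs = c(0.4, 0.6))
#' @export
locus <- function(name, alleles, freqs = NULL, ref_allele = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  alleles <- as.character(alleles)
  if (length(alleles) < 2L || anyDuplicated(alleles))
    stop("a locus needs at least two distinct allele labels")
  if (!is.null(freqs)) {
    freqs <- as.numeric(freqs)
    if (length(freqs) != length(alleles))
      stop("freqs must have one entry per allele")
    if (any(freqs <= 0) || any(freqs >= 1))
      stop("every allele frequency must lie in (0, 1)")
    if (abs(sum(freqs) - 1) > 1e-12)
      stop("allele frequencies must sum to 1 (within 1e-12)")
  }
  if (is.null(ref_allele)) {
    ref_allele <- if (!is.null(freqs)) alleles[which.max(freqs)]
                  else alleles[length(alleles)]
  }
  ref_allele <- as.character(ref_allele)
  if (!ref_allele %in% alleles)
    stop("ref_allele '", ref_allele, "' is not among the declared alleles")
  ord <- c(setdiff(seq_along(alleles), match(ref_allele, alleles)),
           match(ref_allele, alleles))
  structure(list(name = name,
                 alleles = alleles[ord],
                 freqs = if (is.null(freqs)) NULL else freqs[ord],
                 m = length(alleles)),
            class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat("Locus", x$name, "with", x$m, "alleles:",
      paste(x$alleles, collapse = ", "),
      sprintf("(reference: %s)\n", x$alleles[x$m]))
  if (!is.null(x$freqs))
    cat("  frequencies:", paste(format(x$freqs), collapse = ", "), "\n")
  invisible(x)
}

# index pairs (j, k) with j <= k <= mm, in row order (1,1), (1,2), ..., (mm,mm)
pair_index <- function(mm) {
  out <- matrix(0L, nrow = mm * (mm + 1L) / 2L, ncol = 2L)
  i <- 0L
  for (j in seq_len(mm)) for (k in j:mm) {
    i <- i + 1L
    out[i, ] <- c(j, k)
  }
  out
}
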