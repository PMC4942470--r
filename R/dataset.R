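#' Assemble a genotype/phenotype dataset
#'
#' Stores per-individual unordered genotypes at one or two loci, together
#' with an optional numeric phenotype and optional covariates.  Genotypes
#' are normalized to a canonical form: the two allele labels of each
#' genotype are stored as indices into the locus allele list, sorted in
#' increasing order, so that "a/b" and "b/a" are the same genotype.
#'
#' @param genotypes a list with one element per locus.  Each element is
#'   either a character vector of "a/b" genotype strings or an n-by-2
#'   matrix of allele labels (or integer allele indices).
#' @param loci list of [locus()] objects, one per locus (1 or 2).  If
#'   omitted, loci are inferred from the data: alleles sorted by label and
#'   the most frequent allele taken as reference.
#' @param phenotype optional numeric vector of trait values.
#' @param covariates optional data frame of numeric covariates.
#' @param sample_id optional character vector of individual labels.
#' @return An object of class `"genotype_dataset"`: a list with elements
#'   `loci`, `geno` (list of n-by-2 sorted integer matrices), `phenotype`,
#'   `covariates`, `sample_id` and `n`.
#' @examples
#' ds <- genotype_dataset(list(L1 = c("1/1", "1/0", "0/1", "0/0")),
#'                        phenotype = c(2, 1, 1, 0))
#' genotype_counts(ds)
#' @export
genotype_dataset <- function(genotypes, loci = NULL, phenotype = NULL,
                             covariates = NULL, sample_id = NULL) {
  if (!is.list(genotypes)) genotypes <- list(genotypes)
  if (length(genotypes) < 1L || length(genotypes) > 2L)
    stop("only 1 or 2 loci are supported")
  raw <- lapply(genotypes, parse_genotypes)
  n <- nrow(raw[[1L]])
  if (length(raw) == 2L && nrow(raw[[2L]]) != n)
    stop("loci have different numbers of individuals")
  if (n == 0L) stop("no data rows")
  if (is.null(loci)) {
    loci <- lapply(seq_along(raw), function(l) {
      labs <- sort(unique(as.vector(raw[[l]])))
      if (length(labs) < 2L)
        stop("locus ", l, " is monomorphic; declare its alleles explicitly")
      ref <- names(which.max(table(as.vector(raw[[l]]))))
      nm <- names(genotypes)[l]
      if (is.null(nm) || !nzchar(nm)) nm <- paste0("L", l)
      locus(nm, labs, ref_allele = ref)
    })
  } else {
    if (inherits(loci, "locus")) loci <- list(loci)
    stopifnot(length(loci) == length(raw))
  }
  geno <- vector("list", length(raw))
  for (l in seq_along(raw)) {
    idx <- matrix(match(raw[[l]], loci[[l]]$alleles), ncol = 2L)
    if (anyNA(idx)) {
      bad <- unique(raw[[l]][is.na(idx)])
      stop("unknown allele label(s) at locus ", loci[[l]]$name, ": ",
           paste(bad, collapse = ", "))
    }
    geno[[l]] <- cbind(pmin.int(idx[, 1L], idx[, 2L]),
                       pmax.int(idx[, 1L], idx[, 2L]))
  }
  names(geno) <- vapply(loci, `[[`, "", "name")
  if (!is.null(phenotype)) {
    phenotype <- as.numeric(phenotype)
    stopifnot(length(phenotype) == n)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
  }
  if (is.null(sample_id)) sample_id <- as.character(seq_len(n))
  structure(list(loci = loci, geno = geno, phenotype = phenotype,
                 covariates = covariates, sample_id = sample_id, n = n),
            class = "genotype_dataset")
}

# accepts "a/b" strings or an n x 2 matrix; returns n x 2 character matrix
parse_genotypes <- function(g) {
  if (is.matrix(g)) {
    stopifnot(ncol(g) == 2L)
    return(matrix(as.character(g), ncol = 2L))
  }
  g <- as.character(g)
  parts <- strsplit(g, "/", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("genotype strings must be two allele labels separated by '/'")
  matrix(unlist(parts), ncol = 2L, byrow = TRUE)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("Genotype dataset:", x$n, "individuals,", length(x$loci),
      if (length(x$loci) == 1L) "locus" else "loci",
      sprintf("(%s)", paste(vapply(x$loci, `[[`, "", "name"),
                            collapse = ", ")),
      if (is.null(x$phenotype)) "- genotypes only" else "- with phenotype",
      "\n")
  invisible(x)
}

#' Genotype counts at a locus
#'
#' Tallies the symmetric count table n_jk over unordered genotypes: entry
#' (j, k) = (k, j) holds the number of individuals with genotype AjAk, so
#' the diagonal plus the upper triangle sums to the sample size.
#'
#' @param ds a [genotype_dataset()].
#' @param which_locus locus index (1 or 2).
#' @return An m-by-m symmetric integer matrix with allele labels as
#'   dimnames.
#' @export
genotype_counts <- function(ds, which_locus = 1L) {
  stopifnot(inherits(ds, "genotype_dataset"))
  loc <- ds$loci[[which_locus]]
  g <- ds$geno[[which_locus]]
  nm <- matrix(0L, loc$m, loc$m, dimnames = list(loc$alleles, loc$alleles))
  tab <- table(factor(g[, 1L], levels = seq_len(loc$m)),
               factor(g[, 2L], levels = seq_len(loc$m)))
  nm[] <- tab + t(tab) - diag(diag(tab))
  # off-diagonal of tab is only upper triangle (g sorted); diag counted once
  nm
}

#' Joint genotype counts at two loci
#'
#' @param ds a two-locus [genotype_dataset()].
#' @return A 4-dimensional array n_jkrs (m1, m1, m2, m2), symmetric in its
#'   first and in its last two indices; each unordered joint genotype count
#'   is replicated across its symmetric positions.
#' @export
joint_genotype_counts <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"), length(ds$loci) == 2L)
  m1 <- ds$loci[[1L]]$m; m2 <- ds$loci[[2L]]$m
  g1 <- ds$geno[[1L]]; g2 <- ds$geno[[2L]]
  arr <- array(0L, dim = c(m1, m1, m2, m2),
               dimnames = list(ds$loci[[1L]]$alleles, ds$loci[[1L]]$alleles,
                               ds$loci[[2L]]$alleles, ds$loci[[2L]]$alleles))
  for (i in seq_len(ds$n)) {
    # genotype pairs are stored sorted, so this indexes the canonical cell
    arr[g1[i, 1L], g1[i, 2L], g2[i, 1L], g2[i, 2L]] <-
      arr[g1[i, 1L], g1[i, 2L], g2[i, 1L], g2[i, 2L]] + 1L
  }
  for (j in seq_len(m1 - 1L)) for (k in (j + 1L):m1)
    arr[k, j, , ] <- arr[j, k, , ]
  for (r in seq_len(m2 - 1L)) for (s in (r + 1L):m2)
    arr[, , s, r] <- arr[, , r, s]
  arr
}

#' Genotypic group means
#'
#' Cell means of the phenotype over unordered genotype classes: an m-by-m
#' symmetric matrix for one locus, or a (m1, m1, m2, m2) array for two
#' loci.  Cells with no observations are `NA`.
#'
#' @param ds a [genotype_dataset()] with a phenotype.
#' @return A list with elements `means` (matrix or 4-d array), `counts`
#'   (same shape), and `grand_mean`.
#' @export
group_means <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (is.null(ds$phenotype)) stop("dataset has no phenotype")
  y <- ds$phenotype
  if (length(ds$loci) == 1L) {
    loc <- ds$loci[[1L]]; g <- ds$geno[[1L]]
    mn <- matrix(NA_real_, loc$m, loc$m,
                 dimnames = list(loc$alleles, loc$alleles))
    ct <- matrix(0L, loc$m, loc$m, dimnames = dimnames(mn))
    cell <- (g[, 1L] - 1L) * loc$m + g[, 2L]
    sums <- tapply(y, cell, sum)
    ns <- table(cell)
    for (nmc in names(ns)) {
      id <- as.integer(nmc)
      j <- (id - 1L) %/% loc$m + 1L; k <- (id - 1L) %% loc$m + 1L
      mn[j, k] <- mn[k, j] <- sums[[nmc]] / ns[[nmc]]
      ct[j, k] <- ct[k, j] <- as.integer(ns[[nmc]])
    }
    list(means = mn, counts = ct, grand_mean = mean(y))
  } else {
    m1 <- ds$loci[[1L]]$m; m2 <- ds$loci[[2L]]$m
    g1 <- ds$geno[[1L]]; g2 <- ds$geno[[2L]]
    mn <- array(NA_real_, dim = c(m1, m1, m2, m2))
    ct <- array(0L, dim = c(m1, m1, m2, m2))
    key <- paste(g1[, 1L], g1[, 2L], g2[, 1L], g2[, 2L])
    sums <- tapply(y, key, sum)
    ns <- table(key)
    for (nmc in names(ns)) {
      id <- as.integer(strsplit(nmc, " ", fixed = TRUE)[[1L]])
      mn[id[1L], id[2L], id[3L], id[4L]] <- sums[[nmc]] / ns[[nmc]]
      ct[id[1L], id[2L], id[3L], id[4L]] <- as.integer(ns[[nmc]])
    }
    for (j in seq_len(m1 - 1L)) for (k in (j + 1L):m1) {
      mn[k, j, , ] <- mn[j, k, , ]; ct[k, j, , ] <- ct[j, k, , ]
    }
    for (r in seq_len(m2 - 1L)) for (s in (r + 1L):m2) {
      mn[, , s, r] <- mn[, , r, s]; ct[, , s, r] <- ct[, , r, s]
    }
    list(means = mn, counts = ct, grand_mean = mean(y))
  }
}

#' @export
as.data.frame.genotype_dataset <- function(x, ...) {
  out <- data.frame(sample_id = x$sample_id, stringsAsFactors = FALSE)
  for (l in seq_along(x$loci)) {
    loc <- x$loci[[l]]
    out[[loc$name]] <- paste(loc$alleles[x$geno[[l]][, 1L]],
                             loc$alleles[x$geno[[l]][, 2L]], sep = "/")
  }
  if (!is.null(x$phenotype)) out$phenotype <- x$phenotype
  if (!is.null(x$covariates)) out <- cbind(out, x$covariates)
  out
}
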