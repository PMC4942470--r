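#' Read a genotype/phenotype table
#'
#' Reads a delimited text file (TSV or CSV by extension, with a header)
#' with one row per individual: genotype columns holding two allele labels
#' separated by "/", a numeric phenotype column, and optional covariate
#' columns.  Rows with a missing genotype or phenotype (`NA` or empty) are
#' dropped with a message reporting the count.
#'
#' @param path file path.
#' @param genotype_cols names of the genotype columns (1 or 2).  Defaults
#'   to every column that is not the sample id, phenotype or a covariate.
#' @param phenotype_col name of the phenotype column; `NULL` for a
#'   genotypes-only file.
#' @param covariate_cols names of covariate columns to carry along.
#' @param loci optional list of [locus()] objects declaring the alleles;
#'   an allele in the file that is not declared is an error.  If omitted,
#'   loci are inferred from the data.
#' @param sep field separator; inferred from the file extension when
#'   `NULL` ("," for `.csv`, tab otherwise).
#' @return A [genotype_dataset()].
#' @export
read_genotype_table <- function(path, genotype_cols = NULL,
                                phenotype_col = "phenotype",
                                covariate_cols = NULL, loci = NULL,
                                sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path)
  if (is.null(genotype_cols))
    genotype_cols <- setdiff(names(df),
                             c("sample_id", phenotype_col, covariate_cols))
  if (length(genotype_cols) < 1L || length(genotype_cols) > 2L)
    stop("expected 1 or 2 genotype columns, found: ",
         paste(genotype_cols, collapse = ", "))
  missing_geno <- Reduce(`|`, lapply(df[genotype_cols], function(g)
    is.na(g) | g == "" | g == "NA" | g == "./."))
  y <- NULL
  if (!is.null(phenotype_col)) {
    if (!phenotype_col %in% names(df))
      stop("phenotype column '", phenotype_col, "' not found")
    yraw <- df[[phenotype_col]]
    missing_y <- is.na(yraw) | yraw == "" | yraw == "NA"
    suppressWarnings(ynum <- as.numeric(yraw))
    bad <- which(!missing_y & is.na(ynum))
    if (length(bad))
      stop("non-numeric phenotype value '", yraw[bad[1L]], "' in row ",
           bad[1L])
  } else {
    missing_y <- rep(FALSE, nrow(df))
  }
  drop <- missing_geno | missing_y
  if (any(drop))
    message("dropping ", sum(drop), " row(s) with missing genotype or ",
            "phenotype")
  df <- df[!drop, , drop = FALSE]
  if (nrow(df) == 0L) stop("no data rows after dropping missing values")
  if (!is.null(phenotype_col)) y <- as.numeric(df[[phenotype_col]])
  covs <- if (is.null(covariate_cols)) NULL
          else as.data.frame(lapply(df[covariate_cols], as.numeric))
  ids <- if ("sample_id" %in% names(df)) df[["sample_id"]] else NULL
  genotype_dataset(as.list(df[genotype_cols]), loci = loci, phenotype = y,
                   covariates = covs, sample_id = ids)
}

#' Write a genotype/phenotype table
#'
#' Writes the dataset as tab-delimited text with columns `sample_id`, one
#' "a/b" genotype column per locus, `phenotype` (if present) and any
#' covariates.  A write-read round trip preserves genotypes, counts and
#' phenotypes exactly (phenotypes are printed at full precision).
#'
#' @param ds a [genotype_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(ds, path) {
  df <- as.data.frame(ds)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read unphased genotypes from a VCF
#'
#' Imports the GT field of up to two sites from a VCF file.  Phase is
#' always discarded: "0|1" and "1/0" yield the same unordered genotype,
#' matching the unphased premise of the models.  Alleles are labeled by
#' the REF/ALT strings, so multi-allelic sites become multi-allelic loci.
#' Individuals with a missing GT at any selected site are dropped with a
#' warning.
#'
#' @param path VCF file path.
#' @param sample_ids optional character vector restricting the samples.
#' @param site_ids optional character vector of site IDs to select (at
#'   most 2); defaults to the first one or two sites in the file.
#' @return A [genotype_dataset()] without phenotype.
#' @export
read_vcf_unphased <- function(path, sample_ids = NULL, site_ids = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package 'vcfR' is required to read VCF files")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  if (is.null(site_ids)) {
    take <- seq_len(min(2L, nrow(fix)))
  } else {
    if (length(site_ids) > 2L) stop("at most 2 sites may be selected")
    take <- match(site_ids, ids)
    if (anyNA(take)) stop("site id(s) not found: ",
                          paste(site_ids[is.na(take)], collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[take, , drop = FALSE]
  if (!is.null(sample_ids)) {
    keep <- match(sample_ids, colnames(gt))
    if (anyNA(keep)) stop("sample id(s) not found")
    gt <- gt[, keep, drop = FALSE]
  }
  allele_labels <- lapply(take, function(i)
    c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]))
  parse_gt <- function(codes, labels) {
    parts <- strsplit(codes, "[/|]")
    ok <- lengths(parts) == 2L &
      !vapply(parts, function(p) any(p %in% c(".", "")), TRUE) &
      !is.na(codes)
    out <- matrix(NA_character_, length(codes), 2L)
    idx <- do.call(rbind, lapply(parts[ok], as.integer)) + 1L
    out[ok, ] <- matrix(labels[idx], ncol = 2L)
    out
  }
  mats <- lapply(seq_along(take), function(l)
    parse_gt(gt[l, ], allele_labels[[l]]))
  complete <- Reduce(`&`, lapply(mats, function(m) !is.na(m[, 1L])))
  if (!all(complete))
    warning("dropping ", sum(!complete),
            " individual(s) with missing genotype calls")
  if (!any(complete)) stop("no individuals with complete genotype calls")
  mats <- lapply(mats, function(m) m[complete, , drop = FALSE])
  loci <- lapply(seq_along(take), function(l) {
    labs <- allele_labels[[l]]
    seen <- unique(as.vector(mats[[l]]))
    labs <- labs[labs %in% seen]
    if (length(labs) < 2L)
      stop("site ", ids[take[l]], " is monomorphic among selected samples")
    ref <- names(which.max(table(as.vector(mats[[l]]))))
    locus(ids[take[l]], labs, ref_allele = ref)
  })
  geno <- stats::setNames(mats, ids[take])
  genotype_dataset(geno, loci = loci,
                   sample_id = colnames(gt)[complete])
}

#' Exact Hardy-Weinberg fixture dataset
#'
#' Builds a dataset whose empirical genotype counts equal the expected
#' Hardy-Weinberg counts exactly, so every estimated disequilibrium
#' coefficient is exactly zero: the sampling deviation that would
#' otherwise perturb the orthogonality identities is removed by
#' construction.  For two loci the joint counts are the exact products of
#' the per-locus HWE counts, so all joint disequilibrium coefficients
#' vanish as well.
#'
#' Every expected count N p_j^2, 2 N p_j p_k (and their two-locus
#' products) must be a whole number; otherwise an error suggests the
#' smallest sample size that works.
#'
#' @param freqs allele frequency vector (one locus) or list of two such
#'   vectors (two loci); frequencies should be rational for an exact
#'   fixture to exist.
#' @param n total sample size.
#' @param loci optional list of [locus()] objects; by default biallelic or
#'   multi-allelic loci named "L1", "L2" with alleles "a1", "a2", ... are
#'   created with the given frequencies (last allele as reference).
#' @return A [genotype_dataset()] without phenotype.
#' @examples
#' ds <- exact_hwe_fixture(c(0.4, 0.6), 25)
#' genotype_counts(ds)          # 4 / 12 / 9
#' max(abs(hwd_coefficients(ds)))  # exactly 0
#' @export
exact_hwe_fixture <- function(freqs, n, loci = NULL) {
  if (!is.list(freqs)) freqs <- list(freqs)
  stopifnot(length(freqs) %in% c(1L, 2L))
  if (is.null(loci))
    loci <- lapply(seq_along(freqs), function(l)
      locus(paste0("L", l),
            paste0("a", seq_along(freqs[[l]])),
            freqs = freqs[[l]],
            ref_allele = paste0("a", length(freqs[[l]]))))
  if (inherits(loci, "locus")) loci <- list(loci)
  cellw <- lapply(seq_along(freqs), function(l) {
    p <- freqs[[l]]
    cells <- pair_index(length(p))
    w <- ifelse(cells[, 1L] == cells[, 2L],
                p[cells[, 1L]]^2,
                2 * p[cells[, 1L]] * p[cells[, 2L]])
    list(cells = cells, w = w)
  })
  w_joint <- if (length(freqs) == 1L) cellw[[1L]]$w
             else as.vector(outer(cellw[[2L]]$w, cellw[[1L]]$w))
  counts <- n * w_joint
  if (max(abs(counts - round(counts))) > 1e-8) {
    suggest <- NA_integer_
    for (k in seq_len(100000L)) {
      ck <- k * w_joint
      if (max(abs(ck - round(ck))) < 1e-8) { suggest <- k; break }
    }
    stop("expected HWE counts are not integers at n = ", n,
         if (!is.na(suggest)) paste0("; the smallest valid scale is n = ",
                                     suggest)
         else "; no valid scale up to 100000 (are the frequencies rational?)")
  }
  counts <- as.integer(round(counts))
  if (length(freqs) == 1L) {
    cells <- cellw[[1L]]$cells
    g1 <- cells[rep(seq_len(nrow(cells)), counts), , drop = FALSE]
    geno <- list(L1 = matrix(loci[[1L]]$alleles[g1], ncol = 2L))
  } else {
    c1 <- cellw[[1L]]$cells; c2 <- cellw[[2L]]$cells
    grid <- cbind(c1[rep(seq_len(nrow(c1)), each = nrow(c2)), , drop = FALSE],
                  c2[rep(seq_len(nrow(c2)), times = nrow(c1)), , drop = FALSE])
    rows <- grid[rep(seq_len(nrow(grid)), counts), , drop = FALSE]
    geno <- list(L1 = matrix(loci[[1L]]$alleles[rows[, 1:2]], ncol = 2L),
                 L2 = matrix(loci[[2L]]$alleles[rows[, 3:4]], ncol = 2L))
  }
  names(geno) <- vapply(loci, `[[`, "", "name")
  genotype_dataset(geno, loci = loci)
}
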