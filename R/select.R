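#' Forward stepwise selection with entry/stay thresholds
#'
#' Classic forward stepwise regression over a set of candidate columns: at
#' each step the candidate with the smallest partial-F p-value enters if
#' that p-value is below `p_enter`; after each entry, included variables
#' whose partial-F p-value exceeds `p_stay` are removed (largest p first).
#' Selection stops when no variable can enter, or when the removal step
#' undoes the entry just made.  The intercept is always included.  Ties in
#' p-values are broken by candidate column order.
#'
#' All fits are computed from the cross-product matrices, so the cost per
#' step is independent of the sample size once the cross-products are
#' formed.
#'
#' @param y numeric response vector.
#' @param X candidate matrix (no intercept column), with column names.
#' @param p_enter,p_stay entry and stay significance thresholds.
#' @return A list with `selected` (character vector of selected column
#'   names, in entry order) and `steps` (a data frame logging each
#'   action).
#' @export
forward_stepwise <- function(y, X, p_enter = 0.05, p_stay = 0.05) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (n <= ncol(X) + 1L)
    stop("sample size must exceed the number of candidates + 1")
  M <- cbind(`(Intercept)` = 1, X)
  C <- crossprod(M)
  Cy <- as.vector(crossprod(M, y))
  yy <- sum(y * y)
  sse_of <- function(cols) {      # cols: indices into M (1 = intercept)
    A <- C[cols, cols, drop = FALSE]
    b <- tryCatch(solve(A, Cy[cols]), error = function(e) NULL)
    if (is.null(b)) return(NA_real_)
    yy - sum(b * Cy[cols])
  }
  selected <- integer(0)          # indices into columns of X
  steps <- list()
  log_step <- function(var, F, p, action)
    steps[[length(steps) + 1L]] <<- data.frame(variable = var, F = F, p = p,
                                               action = action)
  sse_cur <- sse_of(1L)
  warned <- FALSE
  repeat {
    cand <- setdiff(seq_len(ncol(X)), selected)
    if (length(cand) == 0L) break
    df2 <- n - length(selected) - 2L
    ps <- Fs <- rep(NA_real_, length(cand))
    for (i in seq_along(cand)) {
      sse_new <- sse_of(c(1L, selected + 1L, cand[i] + 1L))
      if (is.na(sse_new)) {
        if (!warned) {
          warning("skipping collinear candidate(s)")
          warned <- TRUE
        }
        next
      }
      Fs[i] <- (sse_cur - sse_new) / (sse_new / df2)
      ps[i] <- stats::pf(Fs[i], 1, df2, lower.tail = FALSE)
    }
    if (all(is.na(ps)) || min(ps, na.rm = TRUE) >= p_enter) break
    best <- which.min(ps)          # first minimum wins: canonical order
    entered <- cand[best]
    selected <- c(selected, entered)
    sse_cur <- sse_of(c(1L, selected + 1L))
    log_step(colnames(X)[entered], Fs[best], ps[best], "enter")
    # removal phase
    removed_entered <- FALSE
    repeat {
      if (length(selected) == 0L) break
      df2r <- n - length(selected) - 1L
      psr <- Fsr <- rep(NA_real_, length(selected))
      for (i in seq_along(selected)) {
        sse_wo <- sse_of(c(1L, selected[-i] + 1L))
        Fsr[i] <- (sse_wo - sse_cur) / (sse_cur / df2r)
        psr[i] <- stats::pf(Fsr[i], 1, df2r, lower.tail = FALSE)
      }
      if (max(psr, na.rm = TRUE) <= p_stay) break
      worst <- which.max(psr)
      leaving <- selected[worst]
      log_step(colnames(X)[leaving], Fsr[worst], psr[worst], "remove")
      selected <- selected[-worst]
      sse_cur <- sse_of(c(1L, selected + 1L))
      if (leaving == entered) {
        removed_entered <- TRUE
        break
      }
    }
    if (removed_entered) break
  }
  list(selected = colnames(X)[selected],
       steps = if (length(steps)) do.call(rbind, steps)
               else data.frame(variable = character(0), F = numeric(0),
                               p = numeric(0), action = character(0)))
}

#' Classify a selected model into types I-X
#'
#' The ten-category taxonomy for selected two-locus models, defined by
#' which of the five leading variables (the two additive mains `w1`, `w2`,
#' their product `ww`, and the two dominance terms `v1`, `v2`) are in the
#' selected set.  Categories are evaluated in order I, II, ..., X and the
#' first match wins, which resolves the overlaps between definitions:
#'
#' * I: all of w1, w2, ww, v1, v2 selected
#' * II: w1, w2, ww, v1 but not v2
#' * III: w1, w2, ww, v2 but not v1
#' * IV: w1, w2, ww but neither v1 nor v2
#' * V: w1, w2 but not ww
#' * VI: w1 and ww but not w2
#' * VII: w2 and ww but not w1
#' * VIII: ww but neither w1 nor w2
#' * IX: exactly one of w1, w2, and no ww
#' * X: w1, w2, ww all missed
#'
#' The same taxonomy applies to the GLM dummy variables and the GMA index
#' variables; extra selected interaction terms never demote a model.
#'
#' @param selected character vector of selected column names.
#' @param keys named character vector giving the column names playing the
#'   roles `w1`, `w2`, `ww`, `v1`, `v2`.
#' @return A single character: "I", "II", ..., "X".
#' @export
classify_model <- function(selected,
                           keys = c(w1 = "w1", w2 = "w2", ww = "ww",
                                    v1 = "v1", v2 = "v2")) {
  stopifnot(all(c("w1", "w2", "ww", "v1", "v2") %in% names(keys)))
  has <- function(k) keys[[k]] %in% selected
  w1 <- has("w1"); w2 <- has("w2"); ww <- has("ww")
  v1 <- has("v1"); v2 <- has("v2")
  if (w1 && w2 && ww && v1 && v2) return("I")
  if (w1 && w2 && ww && v1) return("II")
  if (w1 && w2 && ww && v2) return("III")
  if (w1 && w2 && ww) return("IV")
  if (w1 && w2) return("V")
  if (w1 && ww) return("VI")
  if (w2 && ww) return("VII")
  if (ww) return("VIII")
  if (w1 || w2) return("IX")
  "X"
}

model_types <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X")

#' Model-selection simulation study
#'
#' Replicated forward stepwise selection under the two-locus study model:
#' each replicate simulates `n` individuals from the true model, builds
#' the eight candidate columns in the requested coding (GMA codes use the
#' allele frequencies estimated from the replicate, as in practice),
#' runs [forward_stepwise()], and classifies the selected model.
#'
#' The global seed is expanded into independent per-replicate child seeds,
#' so runs are reproducible and replicates are independent.
#'
#' @param n sample size per replicate.
#' @param reps number of replicates.
#' @param coding `"gma"` or `"glm"` candidate set.
#' @param seed integer seed for the whole study.
#' @param model the true model, as returned by [default_study_model()].
#' @param p_enter,p_stay stepwise thresholds.
#' @return An object of class `"selection_study"`: a named integer vector
#'   of counts over types I-X (summing to `reps`) with the settings as
#'   attributes.
#' @export
run_selection_experiment <- function(n, reps, coding = c("gma", "glm"),
                                     seed = 1L, model = default_study_model(),
                                     p_enter = 0.05, p_stay = 0.05) {
  coding <- match.arg(coding)
  counts <- stats::setNames(integer(length(model_types)), model_types)
  if (reps == 0L)
    return(structure(counts, class = "selection_study", n = n, reps = 0L,
                     coding = coding))
  loci <- model$loci
  stopifnot(length(loci) == 2L, loci[[1L]]$m == 2L, loci[[2L]]$m == 2L)
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  G <- unclass_gv(genotypic_values(model$glm))
  P1 <- genotype_probs(loci[[1L]]$freqs)
  P2 <- genotype_probs(loci[[2L]]$freqs)
  cells <- pair_index(2L)                 # (1,1), (1,2), (2,2)
  w_cell <- c(2, 1, 0)                    # copies of allele 1 per cell
  v_cell <- c(1, 0, 0)
  p_cell1 <- P1[cells]
  p_cell2 <- P2[cells]
  star <- if (coding == "gma") "*" else ""
  labs <- paste0(c("w1", "v1", "w2", "v2", "ww", "wv", "vw", "vv"), star)
  for (rep_i in seq_len(reps)) {
    set.seed(child_seeds[rep_i])
    i1 <- sample.int(3L, n, replace = TRUE, prob = p_cell1)
    i2 <- sample.int(3L, n, replace = TRUE, prob = p_cell2)
    y <- G[cbind(cells[i1, , drop = FALSE], cells[i2, , drop = FALSE])] +
      stats::rnorm(n, 0, sqrt(model$v_eps))
    w1 <- w_cell[i1]; v1 <- v_cell[i1]
    w2 <- w_cell[i2]; v2 <- v_cell[i2]
    if (coding == "gma") {
      p1 <- mean(w1) / 2; p2 <- mean(w2) / 2    # MLE of allele-1 frequency
      ws1 <- w1 - 2 * p1; vs1 <- v1 - p1 * w1 + p1^2
      ws2 <- w2 - 2 * p2; vs2 <- v2 - p2 * w2 + p2^2
      X <- cbind(ws1, vs1, ws2, vs2, ws1 * ws2, ws1 * vs2, vs1 * ws2,
                 vs1 * vs2)
    } else {
      X <- cbind(w1, v1, w2, v2, w1 * w2, w1 * v2, v1 * w2, v1 * v2)
    }
    colnames(X) <- labs
    sel <- forward_stepwise(y, X, p_enter, p_stay)
    type <- classify_model(sel$selected,
                           keys = c(w1 = labs[1L], w2 = labs[3L],
                                    ww = labs[5L], v1 = labs[2L],
                                    v2 = labs[4L]))
    counts[type] <- counts[type] + 1L
  }
  structure(counts, class = "selection_study", n = n, reps = reps,
            coding = coding)
}

#' @export
print.selection_study <- function(x, ...) {
  cat("Stepwise selection study:", attr(x, "reps"), "replicates, n =",
      attr(x, "n"), ", coding =", toupper(attr(x, "coding")), "\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}
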