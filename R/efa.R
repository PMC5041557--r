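## Exploratory factor analysis: principal axis factoring with oblique Geomin
## rotation for the reported loadings, and a parallel maximum-likelihood fit
## (stats::factanal) purely for the chi-square-based fit indices.

## iterated principal axis factoring on a correlation matrix
## tol follows the usual PAF practice of iterating communalities to ~1e-3;
## overfactored models creep toward a Heywood bound and never reach machine
## precision
paf_extract <- function(R, n_factors, max_iter = 1000, tol = 1e-3) {
  p <- ncol(R)
  inv <- tryCatch(solve(R), error = function(e)
    data_error("singular correlation matrix"))
  h2 <- pmin(pmax(1 - 1 / diag(inv), 0.05), 0.995)  # start at SMC
  L <- NULL
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    vals <- pmax(e$values[seq_len(n_factors)], 0)
    L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(vals), n_factors)
    h2_new <- pmin(rowSums(L^2), 0.995)
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      return(list(loadings = L, communalities = h2, iterations = it,
                  converged = TRUE))
    }
    h2 <- h2_new
  }
  operat_error(paste0("principal axis factoring did not converge in ",
                      max_iter, " iterations"), "operat_convergence_error")
}

## chi-square, CFI, TLI, RMSEA from an ML factor fit of the same data
ml_fit_indices <- function(R, n_obs, n_factors) {
  p <- ncol(R)
  dof <- ((p - n_factors)^2 - (p + n_factors)) / 2
  null_chisq <- -(n_obs - 1 - (2 * p + 5) / 6) * determinant(R)$modulus[1]
  null_df <- p * (p - 1) / 2
  if (dof <= 0)
    return(list(chi_square = NA_real_, df = NA_real_, p = NA_real_,
                cfi = NA_real_, tli = NA_real_, rmsea = NA_real_))
  fa <- tryCatch(
    factanal(covmat = R, n.obs = n_obs, factors = n_factors,
             rotation = "none"),
    error = function(e) NULL)
  if (is.null(fa))
    return(list(chi_square = NA_real_, df = dof, p = NA_real_,
                cfi = NA_real_, tli = NA_real_, rmsea = NA_real_))
  chisq <- unname(fa$STATISTIC)
  pval <- unname(fa$PVAL)
  cfi <- 1 - max(chisq - dof, 0) / max(null_chisq - null_df, chisq - dof, 0)
  tli <- (null_chisq / null_df - chisq / dof) / (null_chisq / null_df - 1)
  rmsea <- sqrt(max(chisq - dof, 0) / (dof * (n_obs - 1)))
  list(chi_square = chisq, df = dof, p = pval, cfi = cfi, tli = tli,
       rmsea = rmsea)
}

#' Exploratory factor analysis with PAF extraction and Geomin rotation
#'
#' Extraction is iterated principal axis factoring on the Pearson correlation
#' matrix; the reported pattern matrix is the oblique Geomin rotation of that
#' solution. Fit indices (chi-square with p-value, CFI, TLI, RMSEA) come from
#' a maximum-likelihood factor model of the same correlation matrix fitted at
#' the same number of factors, since the least-squares PAF objective carries
#' no likelihood. TLI can exceed 1 in small samples and is reported as
#' computed.
#'
#' @param data numeric matrix or data frame, areas x items (complete cases
#'   are used; incomplete rows are dropped with a message).
#' @param n_factors number of factors to extract.
#' @param eps Geomin epsilon.
#' @param n_starts,seed rotation random starts (see [rotate_geomin()]).
#' @return An object of class `operat_efa`: `n_factors`, `loadings`
#'   (rotated pattern matrix, items x factors), `Phi`, `unrotated`,
#'   `communalities`, `eigenvalues` (of the correlation matrix), `fit`
#'   (list: `chi_square`, `df`, `p`, `cfi`, `tli`, `rmsea`), `n_obs`,
#'   `items`.
#' @export
fit_efa <- function(data, n_factors, eps = 0.01, n_starts = 10, seed = 1) {
  X <- as.matrix(data)
  if (!is.numeric(X)) arg_error("data must be numeric")
  cc <- stats::complete.cases(X)
  if (!all(cc)) {
    message(sum(!cc), " incomplete row(s) dropped before EFA")
    X <- X[cc, , drop = FALSE]
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p) data_error("need more observations than items")
  if (n_factors < 1) arg_error("n_factors must be >= 1")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    data_error(paste0("constant item(s): ",
                      paste(colnames(X)[sds == 0], collapse = ", ")))
  R <- cor(X)
  ex <- paf_extract(R, n_factors)
  rot <- rotate_geomin(ex$loadings, eps = eps, n_starts = n_starts,
                       seed = seed)
  L <- rot$loadings
  rownames(L) <- colnames(X)
  colnames(L) <- paste0("F", seq_len(n_factors))
  structure(list(
    n_factors = n_factors,
    loadings = L,
    Phi = rot$Phi,
    unrotated = ex$loadings,
    communalities = setNames(ex$communalities, colnames(X)),
    eigenvalues = eigen(R, symmetric = TRUE, only.values = TRUE)$values,
    fit = ml_fit_indices(R, n, n_factors),
    n_obs = n,
    items = colnames(X)), class = "operat_efa")
}

#' @export
print.operat_efa <- function(x, cutoff = 0.4, ...) {
  cat("<operat_efa> ", x$n_factors, " factor(s), ", length(x$items),
      " items, n = ", x$n_obs, "\n", sep = "")
  f <- x$fit
  cat(sprintf("  chi-square %.2f (df %d), p %s, CFI %.2f, TLI %.2f, RMSEA %.2f\n",
              f$chi_square, as.integer(f$df),
              format.pval(f$p, digits = 2), f$cfi, f$tli, f$rmsea))
  L <- round(x$loadings, 2)
  disp <- ifelse(abs(L) < cutoff, "", formatC(L, format = "f", digits = 2))
  dimnames(disp) <- dimnames(L)
  print(disp, quote = FALSE)
  invisible(x)
}

#' Fit-index grid over candidate factor counts
#'
#' @param data areas x items matrix.
#' @param candidate_factors integer vector of factor counts to fit.
#' @inheritParams fit_efa
#' @return Tibble with one row per candidate: `n_factors`, `chi_square`,
#'   `df`, `p`, `cfi`, `tli`, `rmsea`, `n_eigen_gt1`.
#' @export
efa_fit_grid <- function(data, candidate_factors = 1:6, eps = 0.01,
                         n_starts = 10, seed = 1) {
  rows <- lapply(candidate_factors, function(k) {
    m <- fit_efa(data, k, eps = eps, n_starts = n_starts, seed = seed)
    tibble::tibble(n_factors = k, chi_square = m$fit$chi_square,
                   df = m$fit$df, p = m$fit$p, cfi = m$fit$cfi,
                   tli = m$fit$tli, rmsea = m$fit$rmsea,
                   n_eigen_gt1 = sum(m$eigenvalues > 1))
  })
  do.call(rbind, rows)
}

#' Tucker's congruence between two loading matrices
#'
#' Columns of `B` are greedily matched to columns of `A` by absolute
#' congruence (sign flips allowed, each factor used once); returns the
#' per-factor matched congruences and their mean.
#'
#' @param A,B loading matrices with identical row sets (rows are aligned by
#'   name when both are named).
#' @return List with `congruence` (per matched factor, in \[0, 1\]) and
#'   `mean`.
#' @export
tucker_congruence <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!is.null(rownames(A)) && !is.null(rownames(B)))
    B <- B[rownames(A), , drop = FALSE]
  stopifnot(nrow(A) == nrow(B))
  C <- crossprod(A, B) /
    sqrt(outer(colSums(A^2), colSums(B^2)))
  k <- min(ncol(A), ncol(B))
  used_a <- used_b <- integer(0)
  vals <- numeric(k)
  Cw <- abs(C)
  for (i in seq_len(k)) {
    Cw[used_a, ] <- -Inf
    if (length(used_b)) Cw[, used_b] <- -Inf
    idx <- arrayInd(which.max(Cw), dim(Cw))
    vals[i] <- abs(C[idx[1], idx[2]])
    used_a <- c(used_a, idx[1]); used_b <- c(used_b, idx[2])
    Cw <- abs(C); Cw[used_a, ] <- -Inf; Cw[, used_b] <- -Inf
  }
  list(congruence = vals, mean = mean(vals))
}
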