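## Oblique Geomin rotation by gradient projection.
##
## The Geomin criterion for a p x k loading matrix L is
##   Q(L) = sum_i ( prod_j (L_ij^2 + eps) )^(1/k),
## minimised over oblique rotations L = A (T')^{-1} with the columns of T of
## unit length. The minimiser is found with the gradient-projection algorithm
## (projection of the gradient onto the manifold of unit-column matrices,
## with step halving), restarted from several random rotations because the
## criterion is not convex.

geomin_criterion <- function(L, eps = 0.01) {
  k <- ncol(L)
  L2 <- L^2 + eps
  pro <- exp(rowSums(log(L2)) / k)
  list(f = sum(pro), G = (2 / k) * (L / L2) * pro)
}

gpa_oblique <- function(A, Tmat, eps = 0.01, maxit = 500, tol = 1e-6) {
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  v <- geomin_criterion(L, eps)
  f <- v$f
  G <- -t(t(L) %*% v$G %*% Ti)
  al <- 1
  s <- Inf
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), ncol(Tmat))
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    improved <- FALSE
    for (half in 1:30) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(X))
      Ti2 <- tryCatch(solve(Tt), error = function(e) NULL)
      if (!is.null(Ti2)) {
        L2 <- A %*% t(Ti2)
        v2 <- geomin_criterion(L2, eps)
        if (v2$f < f - 0.5 * s^2 * al) { improved <- TRUE; break }
      }
      al <- al / 2
    }
    if (!improved) break
    Tmat <- Tt; Ti <- Ti2; L <- L2; f <- v2$f
    G <- -t(t(L) %*% v2$G %*% Ti)
  }
  list(loadings = L, Phi = t(Tmat) %*% Tmat, Tmat = Tmat, f = f,
       iterations = iter, converged = s < tol)
}

random_start <- function(k) {
  M <- matrix(rnorm(k * k), k, k)
  Q <- qr.Q(qr(M))
  Q %*% diag(1 / sqrt(colSums(Q^2)), k)
}

#' Geomin-rotate a factor loading matrix
#'
#' Oblique Geomin rotation (gradient projection with multiple seeded random
#' starts; the solution with the lowest criterion value is kept). Factors are
#' ordered by decreasing sum of squared loadings and sign-flipped so each
#' factor's largest loading is positive.
#'
#' @param A unrotated p x k loading matrix.
#' @param eps Geomin epsilon (default 0.01).
#' @param n_starts random starts in addition to the identity start.
#' @param seed integer seed for the random starts.
#' @return List: `loadings` (rotated pattern matrix), `Phi` (factor
#'   correlations), `f` (criterion value), `converged`.
#' @export
rotate_geomin <- function(A, eps = 0.01, n_starts = 10, seed = 1) {
  k <- ncol(A)
  if (k == 1L)
    return(list(loadings = A, Phi = matrix(1, 1, 1), f = NA_real_,
                converged = TRUE))
  starts <- c(list(diag(k)), local({
    old <- .Random.seed_safe()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    lapply(seq_len(n_starts), function(i) random_start(k))
  }))
  fits <- lapply(starts, function(Tm)
    tryCatch(gpa_oblique(A, Tm, eps = eps), error = function(e) NULL))
  fits <- Filter(function(f) !is.null(f) && is.finite(f$f), fits)
  if (!length(fits)) data_error("Geomin rotation failed from every start")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "f"))]]

  L <- best$loadings; Phi <- best$Phi
  ord <- order(-colSums(L^2))
  L <- L[, ord, drop = FALSE]; Phi <- Phi[ord, ord, drop = FALSE]
  for (j in seq_len(k)) {
    if (L[which.max(abs(L[, j])), j] < 0) {
      L[, j] <- -L[, j]
      Phi[j, ] <- -Phi[j, ]; Phi[, j] <- -Phi[, j]
    }
  }
  list(loadings = L, Phi = Phi, f = best$f, converged = best$converged)
}

## save/restore the global RNG state so seeded subroutines do not perturb
## the caller's stream
.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
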