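# Potts model inference: asymmetric pseudo-likelihood maximization (plmDCA)
# and the mean-field (naive inversion) solver used inside paralog matching.

#' Fit configuration for pseudo-likelihood DCA
#'
#' @param lambda_h L2 penalty on fields (default 0.01).
#' @param lambda_J L2 penalty on each coupling block (default 0.01). Both are
#'   on the per-effective-sequence scale: the weighted negative
#'   log-pseudolikelihood is divided by `n_eff` before the penalties are
#'   added, so lambda does not need rescaling with alignment depth.
#' @param gradient_tolerance convergence threshold on the max-norm of the
#'   per-site objective gradient (default 1e-5).
#' @param max_iterations L-BFGS iteration cap per site (default 1000).
#' @param identity_threshold reweighting radius recorded with the fit
#'   (default 0.90).
#' @return A list of class `coevo_fit_config`.
#' @export
fit_config <- function(lambda_h = 0.01, lambda_J = 0.01,
                       gradient_tolerance = 1e-5, max_iterations = 1000L,
                       identity_threshold = 0.90) {
  stopifnot(lambda_h >= 0, lambda_J >= 0, gradient_tolerance > 0,
            max_iterations >= 1)
  structure(list(lambda_h = lambda_h, lambda_J = lambda_J,
                 gradient_tolerance = gradient_tolerance,
                 max_iterations = as.integer(max_iterations),
                 identity_threshold = identity_threshold),
            class = "coevo_fit_config")
}

# Memoised objective/gradient pair around the compiled kernel: optim() calls
# fn and gr separately with the same parameters, so cache the last evaluation.
plm_site_objective <- function(X, w, site, q, lambda_h, lambda_J, n_eff) {
  last_theta <- NULL
  last_val <- NULL
  evaluate <- function(theta) {
    if (is.null(last_theta) || !identical(theta, last_theta)) {
      last_val <<- cpp_plm_obj_grad(theta, X, w, site, q, lambda_h, lambda_J,
                                    n_eff)
      last_theta <<- theta
    }
    last_val
  }
  list(fn = function(theta) evaluate(theta)$value,
       gr = function(theta) evaluate(theta)$grad)
}

#' Fit a Potts model by asymmetric pseudo-likelihood maximization
#'
#' For each position i independently, maximizes the reweighted conditional
#' log-likelihood of column i given all others, with L2 penalties on fields
#' and couplings (plmDCA). The two directed coupling estimates for each pair
#' are then symmetrized by their arithmetic mean.
#'
#' @param aln a `coevo_alignment` with at least two sequences.
#' @param weights a `coevo_weights` from [compute_weights()]; computed with
#'   `config$identity_threshold` when missing.
#' @param config a [fit_config()].
#' @return A `coevo_potts` model (q = 21, gap included as a state).
#' @export
fit_plm <- function(aln, weights = NULL, config = fit_config()) {
  stopifnot(inherits(aln, "coevo_alignment"))
  if (aln$M < 2L) abort("pseudo-likelihood fitting needs at least 2 sequences")
  if (is.null(weights)) {
    weights <- compute_weights(aln, config$identity_threshold)
  }
  stopifnot(inherits(weights, "coevo_weights"), length(weights$w) == aln$M)
  L <- aln$L
  q <- N_STATES
  h <- matrix(0, L, q)
  J <- array(0, dim = c(q, q, L, L))
  Jdir <- array(0, dim = c(q, q, L, L)) # directed estimates: [, , i, j] from site-i fit
  for (i in seq_len(L)) {
    obj <- plm_site_objective(aln$matrix, weights$w, i, q,
                              config$lambda_h, config$lambda_J, weights$n_eff)
    theta0 <- numeric(q + (L - 1L) * q * q)
    opt <- optim(theta0, fn = obj$fn, gr = obj$gr, method = "L-BFGS-B",
                 control = list(maxit = config$max_iterations,
                                pgtol = config$gradient_tolerance,
                                factr = 10))
    gnorm <- max(abs(obj$gr(opt$par)))
    if (opt$convergence != 0 && gnorm > config$gradient_tolerance) {
      abort(sprintf(
        "site %d did not converge in %d iterations (gradient max-norm %.3g)",
        i, config$max_iterations, gnorm))
    }
    h[i, ] <- opt$par[seq_len(q)]
    others <- setdiff(seq_len(L), i)
    blocks <- array(opt$par[-seq_len(q)], dim = c(q, q, L - 1L))
    Jdir[, , i, others] <- blocks
  }
  for (i in seq_len(L - 1L)) {
    for (j in seq.int(i + 1L, L)) {
      K <- (Jdir[, , i, j] + t(Jdir[, , j, i])) / 2
      J[, , i, j] <- K
      J[, , j, i] <- t(K)
    }
  }
  new_potts(h, J, check = FALSE)
}

#' Fit a Potts model by mean-field inversion
#'
#' Computes pseudocount-regularized weighted single-site and pairwise state
#' frequencies, forms the connected-correlation matrix over q-1 states per
#' position (the gap state is the reference), and takes the couplings as the
#' negative inverse of that matrix — the classic mean-field DCA solver. Fast
#' but approximate; it is the inner solver of the paralog-matching loop.
#'
#' @param aln a `coevo_alignment` with at least two sequences.
#' @param weights a `coevo_weights`; uniform weights when missing.
#' @param pseudocount relative weight on uniform frequencies in `[0, 1]`
#'   (default 0.5).
#' @return A `coevo_potts` model.
#' @export
fit_mean_field <- function(aln, weights = NULL, pseudocount = 0.5) {
  stopifnot(inherits(aln, "coevo_alignment"),
            pseudocount >= 0, pseudocount <= 1)
  if (aln$M < 2L) abort("mean-field fitting needs at least 2 sequences")
  if (is.null(weights)) {
    weights <- structure(list(w = rep(1, aln$M), n_eff = aln$M),
                         class = "coevo_weights")
  }
  L <- aln$L
  q <- N_STATES
  M <- aln$M
  w <- weights$w / sum(weights$w)
  # sparse one-hot encoding: M x (L*q)
  Z <- Matrix::sparseMatrix(
    i = rep(seq_len(M), L),
    j = as.vector(aln$matrix + q * (rep(seq_len(L), each = M) - 1L)),
    x = 1, dims = c(M, L * q))
  Fmat <- as.matrix(Matrix::crossprod(Z, w * Z)) # (Lq) x (Lq) raw freqs
  f1 <- Matrix::colSums(w * Z)
  pc <- pseudocount
  f1 <- (1 - pc) * f1 + pc / q
  Freg <- (1 - pc) * Fmat + pc / q^2
  # diagonal blocks carry delta structure: f_ii(a,b) = delta_ab * f_i(a)
  for (i in seq_len(L)) {
    idx <- (i - 1L) * q + seq_len(q)
    Freg[idx, idx] <- diag(f1[idx])
  }
  keep <- as.vector(outer(seq_len(q - 1L), (seq_len(L) - 1L) * q, `+`))
  C <- Freg[keep, keep] - tcrossprod(f1[keep])
  invC <- tryCatch(solve(C), error = function(e) {
    abort(paste0("singular correlation matrix; increase the pseudocount ",
                 "(currently ", format(pc), ")"))
  })
  J <- array(0, dim = c(q, q, L, L))
  qr1 <- q - 1L
  for (i in seq_len(L - 1L)) {
    ri <- (i - 1L) * qr1 + seq_len(qr1)
    for (j in seq.int(i + 1L, L)) {
      rj <- (j - 1L) * qr1 + seq_len(qr1)
      K <- matrix(0, q, q)
      K[seq_len(qr1), seq_len(qr1)] <- -invC[ri, rj]
      J[, , i, j] <- K
      J[, , j, i] <- t(K)
    }
  }
  # fields from the independent-site (mean-field) relation, gap as reference
  h <- matrix(0, L, q)
  f1m <- matrix(f1, nrow = q) # q x L
  for (i in seq_len(L)) {
    hi <- log(f1m[, i] / f1m[q, i])
    for (j in seq_len(L)) {
      if (j == i) next
      hi <- hi - J[, , i, j] %*% f1m[, j]
    }
    h[i, ] <- hi - hi[q]
  }
  new_potts(h, J, check = FALSE)
}
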