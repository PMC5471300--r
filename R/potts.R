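# Potts model container and gauge operations.
#
# The model assigns each sequence X the probability
#   P(X) = exp( sum_i h_i(X_i) + sum_{i<j} J_ij(X_i, X_j) ) / Z,
# with per-position fields h (L x q) and pairwise couplings J stored as a
# dense [q, q, L, L] array, J[a, b, i, j] being the coupling between state a
# at position i and state b at position j. Both directions are stored, so
# J[, , i, j] == t(J[, , j, i]) and J[, , i, i] == 0.

#' Construct a Potts model
#'
#' @param h numeric L x q matrix of fields.
#' @param J numeric `[q, q, L, L]` array of couplings; must satisfy
#'   `J[, , i, j] == t(J[, , j, i])` with zero diagonal blocks.
#' @param check validate symmetry (disable for internally built models).
#' @return An object of class `coevo_potts` with fields `h`, `J`, `L`, `q`.
#' @export
new_potts <- function(h, J, check = TRUE) {
  stopifnot(is.matrix(h), is.array(J), length(dim(J)) == 4L)
  L <- nrow(h); q <- ncol(h)
  stopifnot(identical(dim(J), c(q, q, L, L)))
  if (anyNA(h) || anyNA(J) || any(!is.finite(h)) || any(!is.finite(J))) {
    abort("Potts parameters must be finite")
  }
  if (check) {
    for (i in seq_len(L)) {
      if (any(J[, , i, i] != 0)) abort("diagonal coupling blocks must be zero")
      for (j in seq_len(L)) {
        if (max(abs(J[, , i, j] - t(J[, , j, i]))) > 1e-8) {
          abort("couplings must satisfy J[,,i,j] == t(J[,,j,i])")
        }
      }
    }
  }
  structure(list(h = h, J = J, L = L, q = q), class = "coevo_potts")
}

#' @export
print.coevo_potts <- function(x, ...) {
  cat(sprintf("<coevo_potts> L = %d positions, q = %d states\n", x$L, x$q))
  cat(sprintf("  ||h|| = %.3g, sum_ij ||J_ij||^2 = %.3g\n",
              sqrt(sum(x$h^2)), sum(x$J^2) / 2))
  invisible(x)
}

#' Model-level summary
#'
#' @param x a `coevo_potts`.
#' @param ... unused.
#' @return One-row tibble with `L`, `q`, `h_norm`, `J_norm`.
#' @export
glance.coevo_potts <- function(x, ...) {
  tibble(L = x$L, q = x$q, h_norm = sqrt(sum(x$h^2)),
         J_norm = sqrt(sum(x$J^2) / 2))
}

#' Unnormalized sequence energy under a Potts model
#'
#' Returns `sum_i h_i(x_i) + sum_{i<j} J_ij(x_i, x_j)`, i.e. `log P(X)` up to
#' the partition-function constant.
#'
#' @param model a `coevo_potts`.
#' @param sequence integer codes of length L.
#' @return A scalar energy (log unnormalized probability).
#' @export
sequence_energy <- function(model, sequence) {
  stopifnot(length(sequence) == model$L)
  L <- model$L
  e <- sum(model$h[cbind(seq_len(L), sequence)])
  for (i in seq_len(L - 1L)) {
    for (j in seq.int(i + 1L, L)) {
      e <- e + model$J[sequence[i], sequence[j], i, j]
    }
  }
  e
}

#' Conditional log-probabilities at one site
#'
#' The pseudo-likelihood building block: `log P(X_i = a | X_-i)` for all q
#' states `a`, proportional to `h_i(a) + sum_{j != i} J_ij(a, X_j)` and
#' normalized over states.
#'
#' @param model a `coevo_potts`.
#' @param sequence integer codes of length L (the value at `position` is
#'   ignored).
#' @param position site index in 1..L.
#' @return Numeric vector of q log-probabilities summing to one after
#'   exponentiation.
#' @export
site_conditional_logprob <- function(model, sequence, position) {
  stopifnot(position >= 1L, position <= model$L,
            length(sequence) == model$L,
            all(sequence >= 1L), all(sequence <= model$q))
  e <- model$h[position, ]
  for (j in seq_len(model$L)) {
    if (j == position) next
    e <- e + model$J[, sequence[j], position, j]
  }
  e - log_sum_exp(e)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Transform a Potts model to the zero-sum gauge
#'
#' The Potts parameterization is redundant: per-state offsets can be moved
#' between J and h without changing sequence probabilities. Scoring requires
#' the canonical representative in which every coupling block has zero row
#' and column means over states; the compensating per-state shifts are folded
#' into the fields (constant offsets are absorbed by the partition function).
#'
#' @param model a `coevo_potts`.
#' @return An equivalent `coevo_potts` in the zero-sum gauge.
#' @export
zero_sum_gauge <- function(model) {
  h <- model$h
  J <- model$J
  L <- model$L
  if (L >= 2L) {
    for (i in seq_len(L - 1L)) {
      for (j in seq.int(i + 1L, L)) {
        K <- J[, , i, j]
        rm <- rowMeans(K); cm <- colMeans(K); mm <- mean(K)
        Kc <- K - outer(rm, rep(1, model$q)) -
          outer(rep(1, model$q), cm) + mm
        J[, , i, j] <- Kc
        J[, , j, i] <- t(Kc)
        h[i, ] <- h[i, ] + rm
        h[j, ] <- h[j, ] + cm
        # the leftover constant -mm per pair shifts log Z only
      }
    }
  }
  new_potts(h, J, check = FALSE)
}

# Double-center a square matrix (zero row and column means). Used for
# gauge-unambiguous Frobenius scoring of single blocks.
double_center <- function(K) {
  K - rowMeans(K) - rep(colMeans(K), each = nrow(K)) + mean(K)
}
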