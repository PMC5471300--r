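# From couplings to ranked contacts: gap-excluded Frobenius norms, the
# average product correction (symmetric and asymmetric), separation
# filtering / top-N retention, and the depth-normalized inter-protein score.

new_score_matrix <- function(S, kind, partition = NULL) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S),
            kind %in% c("raw", "apc", "normalized"))
  if (kind == "normalized" && is.null(partition)) {
    abort("normalized scores require a partition")
  }
  if (!is.null(partition)) {
    stopifnot(partition >= 1, partition < nrow(S))
    partition <- as.integer(partition)
  }
  diag(S) <- NA_real_
  structure(list(S = S, kind = kind, partition = partition, L = nrow(S)),
            class = "coevo_scores")
}

#' @export
print.coevo_scores <- function(x, ...) {
  cat(sprintf("<coevo_scores> %d x %d, kind = %s", x$L, x$L, x$kind))
  if (!is.null(x$partition)) {
    cat(sprintf(", partition at column %d", x$partition))
  }
  cat("\n")
  invisible(x)
}

#' Tidy a score matrix into long form
#'
#' @param x a `coevo_scores`.
#' @param ... unused.
#' @return Tibble with one row per unordered pair: `i`, `j` (i < j), `score`,
#'   and `inter` (logical; `NA`-free only when a partition is set).
#' @export
tidy.coevo_scores <- function(x, ...) {
  idx <- which(upper.tri(x$S), arr.ind = TRUE)
  out <- tibble(i = idx[, "row"], j = idx[, "col"], score = x$S[idx])
  out$inter <- if (is.null(x$partition)) NA else
    out$i <= x$partition & out$j > x$partition
  dplyr::arrange(out, .data$i, .data$j)
}

#' Frobenius-norm coupling scores
#'
#' The raw co-evolution score `S_ij` is the Frobenius norm of the coupling
#' block `J_ij` in the zero-sum gauge. With `exclude_gap` (the default and
#' the recommended scheme) the block is first restricted to the 20 x 20
#' non-gap states and the gauge is computed on that block, so couplings that
#' live in gap rows or columns — typically artifacts of long gap stretches —
#' contribute nothing.
#'
#' @param model a `coevo_potts`.
#' @param exclude_gap drop gap-state couplings before scoring (default TRUE).
#' @param partition optional column index separating two concatenated
#'   families, carried into the score object.
#' @return A `coevo_scores` of kind `"raw"`.
#' @export
frobenius_scores <- function(model, exclude_gap = TRUE, partition = NULL) {
  stopifnot(inherits(model, "coevo_potts"))
  L <- model$L
  block <- if (exclude_gap) seq_len(model$q - 1L) else seq_len(model$q)
  S <- matrix(0, L, L)
  if (L >= 2L) {
    for (i in seq_len(L - 1L)) {
      for (j in seq.int(i + 1L, L)) {
        K <- double_center(model$J[block, block, i, j])
        S[i, j] <- S[j, i] <- sqrt(sum(K^2))
      }
    }
  }
  new_score_matrix(S, "raw", partition)
}

apc_block <- function(S) {
  # symmetric APC on a square score matrix with NA diagonal
  n <- nrow(S)
  if (n < 2L) return(S)
  row_mean <- rowMeans(S, na.rm = TRUE)
  overall <- mean(S[upper.tri(S)])
  if (overall == 0) {
    if (all(S[upper.tri(S)] == 0)) return(S)
    abort("degenerate score matrix: zero mean with nonzero entries")
  }
  out <- S - outer(row_mean, row_mean) / overall
  diag(out) <- NA_real_
  out
}

#' Average product correction
#'
#' Subtracts the background term `rowmean_i * rowmean_j / overallmean` from
#' each score, removing position-specific effects (conservation, entropy)
#' that inflate whole rows of the raw score matrix. Row means exclude the
#' diagonal.
#'
#' @param scores a `coevo_scores` of kind `"raw"`.
#' @return A `coevo_scores` of kind `"apc"`.
#' @export
apc_correct <- function(scores) {
  stopifnot(inherits(scores, "coevo_scores"))
  if (scores$kind != "raw") abort("APC expects raw scores")
  new_score_matrix(apc_block(scores$S), "apc", scores$partition)
}

#' Asymmetric average product correction for two concatenated families
#'
#' For inter-family pairs the two APC averages are taken over the two
#' families separately — `S_ij - (mean of S_i. over family B) * (mean of S_.j
#' over family A) / (mean over all A x B pairs)` — which accommodates
#' different evolutionary rates in the two families. Intra-family blocks are
#' corrected with the symmetric rule.
#'
#' @param scores a `coevo_scores` of kind `"raw"` with a partition set.
#' @return A `coevo_scores` of kind `"apc"`.
#' @export
apc_correct_asymmetric <- function(scores) {
  stopifnot(inherits(scores, "coevo_scores"))
  if (scores$kind != "raw") abort("APC expects raw scores")
  if (is.null(scores$partition)) abort("asymmetric APC requires a partition")
  p <- scores$partition
  L <- scores$L
  A <- seq_len(p)
  B <- seq.int(p + 1L, L)
  S <- scores$S
  out <- S
  out[A, A] <- apc_block(S[A, A, drop = FALSE])
  out[B, B] <- apc_block(S[B, B, drop = FALSE])
  inter <- S[A, B, drop = FALSE]
  overall <- mean(inter)
  if (overall == 0 && any(inter != 0)) {
    abort("degenerate score matrix: zero inter mean with nonzero entries")
  }
  corr <- if (overall == 0) inter else
    inter - outer(rowMeans(inter), colMeans(inter)) / overall
  out[A, B] <- corr
  out[B, A] <- t(corr)
  new_score_matrix(out, "apc", p)
}

#' Rank and retain top-scoring residue pairs
#'
#' Intra-family candidates are all pairs at chain separation
#' `j - i >= min_separation` (short-range pairs are trivially in contact and
#' are excluded to favor long-range structural signal); when a partition is
#' set the candidates are all inter-family pairs with no separation rule.
#' The top `floor(top_n * top_n_multiplier)` candidates by descending score
#' are retained, ties broken lexicographically by (i, j).
#'
#' @param scores a `coevo_scores` of kind `"apc"` or `"normalized"`.
#' @param min_separation minimum chain separation (default 5).
#' @param top_n number of pairs to keep; defaults to L, the standard
#'   retention of as many contacts as alignment columns.
#' @param top_n_multiplier retention scale factor (e.g. 2 to keep double the
#'   usual amount; default 1).
#' @return A `coevo_contacts` object: list with tibble `pairs`
#'   (`i`, `j`, `score`, `rank`), `min_separation`, `retained`, `partition`.
#' @export
rank_contacts <- function(scores, min_separation = 5L, top_n = NULL,
                          top_n_multiplier = 1) {
  stopifnot(inherits(scores, "coevo_scores"))
  if (!scores$kind %in% c("apc", "normalized")) {
    abort("rank_contacts expects APC-corrected or normalized scores")
  }
  L <- scores$L
  if (is.null(top_n)) top_n <- L
  idx <- which(upper.tri(scores$S), arr.ind = TRUE)
  cand <- tibble(i = idx[, "row"], j = idx[, "col"],
                 score = scores$S[idx])
  if (is.null(scores$partition)) {
    cand <- dplyr::filter(cand, .data$j - .data$i >= min_separation)
  } else {
    p <- scores$partition
    cand <- dplyr::filter(cand, .data$i <= p & .data$j > p)
  }
  cand <- dplyr::arrange(cand, dplyr::desc(.data$score), .data$i, .data$j)
  n_keep <- floor(top_n * top_n_multiplier)
  if (n_keep > nrow(cand)) {
    inform(sprintf("only %d candidate pairs available (%d requested)",
                   nrow(cand), n_keep))
    n_keep <- nrow(cand)
  }
  pairs <- utils::head(cand, n_keep)
  pairs$rank <- seq_len(nrow(pairs))
  structure(list(pairs = pairs, min_separation = as.integer(min_separation),
                 retained = nrow(pairs), n_candidates = nrow(cand),
                 partition = scores$partition),
            class = "coevo_contacts")
}

#' @export
print.coevo_contacts <- function(x, ...) {
  cat(sprintf("<coevo_contacts> %d retained of %d candidates (min |i-j| = %d)\n",
              x$retained, x$n_candidates, x$min_separation))
  print(utils::head(x$pairs, 5))
  invisible(x)
}

#' @export
tidy.coevo_contacts <- function(x, ...) x$pairs

#' @export
glance.coevo_contacts <- function(x, ...) {
  tibble(retained = x$retained, n_candidates = x$n_candidates,
         min_separation = x$min_separation,
         top_score = if (x$retained > 0) x$pairs$score[1] else NA_real_)
}

#' Depth- and length-normalized inter-family scores
#'
#' Rescales the APC-corrected inter-family scores as
#' `S~_ij = S_ij / ( |min over inter pairs of S| * (1 + n / n_eff) )`,
#' which partially removes the dependence of coupling scores on protein
#' length and alignment depth so that a fixed acceptance threshold can be
#' shared across protein families. Intra-family entries are left untouched;
#' the inter-pair ranking is unchanged (positive monotone map).
#'
#' @param scores a `coevo_scores` of kind `"apc"` with partition set.
#' @param n alignment length (columns of the concatenated MSA).
#' @param n_eff effective sequence count of the concatenated MSA.
#' @return A `coevo_scores` of kind `"normalized"`.
#' @export
normalized_inter_score <- function(scores, n, n_eff) {
  stopifnot(inherits(scores, "coevo_scores"), n > 0, n_eff > 0)
  if (scores$kind != "apc") abort("normalization expects APC-corrected scores")
  if (is.null(scores$partition)) abort("normalization requires a partition")
  p <- scores$partition
  A <- seq_len(p)
  B <- seq.int(p + 1L, scores$L)
  inter_min <- min(scores$S[A, B])
  if (inter_min == 0) {
    abort("degenerate inter scores: minimum is exactly zero")
  }
  denom <- abs(inter_min) * (1 + n / n_eff)
  S <- scores$S
  S[A, B] <- S[A, B] / denom
  S[B, A] <- t(S[A, B, drop = FALSE])
  new_score_matrix(S, "normalized", p)
}
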