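# Iterative Paralog Matching (IPA): pair interacting paralogs of two protein
# families within each organism so that the inter-family co-evolutionary
# signal is self-consistently maximized, then read off inter-protein contact
# predictions from repeated runs.

#' Bundle two paralog families for matching
#'
#' Both alignments must carry organism labels; organisms present on only one
#' side are excluded from matching.
#'
#' @param alnA,alnB `coevo_alignment` objects for families A and B.
#' @return A `coevo_paired`: list with `alnA`, `alnB`, and `index`, a tibble
#'   with one row per shared organism and list-columns `idxA`, `idxB` of
#'   member row indices.
#' @export
paired_families <- function(alnA, alnB) {
  stopifnot(inherits(alnA, "coevo_alignment"), inherits(alnB, "coevo_alignment"))
  if (!any(nzchar(alnA$organisms)) || !any(nzchar(alnB$organisms))) {
    abort("both alignments need organism labels for paralog matching")
  }
  orgsA <- split(seq_len(alnA$M), alnA$organisms)
  orgsB <- split(seq_len(alnB$M), alnB$organisms)
  shared <- sort(intersect(names(orgsA)[nzchar(names(orgsA))],
                           names(orgsB)[nzchar(names(orgsB))]))
  index <- tibble(
    organism = shared,
    idxA = unname(orgsA[shared]),
    idxB = unname(orgsB[shared])
  )
  structure(list(alnA = alnA, alnB = alnB, index = index),
            class = "coevo_paired")
}

#' @export
print.coevo_paired <- function(x, ...) {
  cat(sprintf("<coevo_paired> %d + %d sequences, %d shared organisms, n_max = %d\n",
              x$alnA$M, x$alnB$M, nrow(x$index), n_max(x)))
  invisible(x)
}

#' Maximum number of matchable sequence pairs
#'
#' Sums `min(N_A, N_B)` over organisms: in each organism, every paralog of
#' the family with fewer members can be matched to exactly one paralog of
#' the other family.
#'
#' @param families a `coevo_paired`.
#' @return Integer.
#' @export
n_max <- function(families) {
  stopifnot(inherits(families, "coevo_paired"))
  sum(pmin(lengths(families$index$idxA), lengths(families$index$idxB)))
}

#' IPA configuration
#'
#' @param n_increment pairs added to the selection size per iteration
#'   (default 6).
#' @param n_runs number of independent IPA runs for acceptance counting.
#' @param pseudocount mean-field pseudocount for the inner solver
#'   (default 0.5).
#' @param score_threshold normalized-score acceptance threshold; pairs with
#'   normalized score strictly above it are accepted (default 0.8).
#' @param identity_threshold reweighting radius (default 0.90).
#' @param rng_seed master seed; per-run child seeds are spawned by counter.
#' @param fit final-model fit configuration, a [fit_config()].
#' @return A list of class `coevo_ipa_config`.
#' @export
ipa_config <- function(n_increment = 6L, n_runs = 10L, pseudocount = 0.5,
                       score_threshold = 0.8, identity_threshold = 0.90,
                       rng_seed = 1L, fit = fit_config()) {
  stopifnot(n_increment >= 1, n_runs >= 1)
  structure(list(n_increment = as.integer(n_increment),
                 n_runs = as.integer(n_runs), pseudocount = pseudocount,
                 score_threshold = score_threshold,
                 identity_threshold = identity_threshold,
                 rng_seed = as.integer(rng_seed), fit = fit),
            class = "coevo_ipa_config")
}

#' Random within-organism seed matching
#'
#' Starts the procedure: within each organism, `min(N_A, N_B)` uniformly
#' random one-to-one pairs. Uses the R RNG, so `set.seed()` makes it
#' reproducible.
#'
#' @param families a `coevo_paired`.
#' @return Tibble of matched pairs: `organism`, `seqA`, `seqB` (row indices
#'   into the two alignments).
#' @export
seed_matching <- function(families) {
  stopifnot(inherits(families, "coevo_paired"))
  if (n_max(families) < 1L) abort("no shared organisms to match")
  purrr::pmap_dfr(families$index, function(organism, idxA, idxB) {
    k <- min(length(idxA), length(idxB))
    tibble(organism = organism,
           seqA = sample_vec(idxA, k),
           seqB = sample_vec(idxB, k))
  })
}

# sample() without the scalar-x surprise
sample_vec <- function(x, k) x[sample.int(length(x), k)]

# Concatenated matched alignment: A columns then B columns, one row per pair.
concat_matched <- function(families, pairs) {
  mat <- cbind(families$alnA$matrix[pairs$seqA, , drop = FALSE],
               families$alnB$matrix[pairs$seqB, , drop = FALSE])
  new_alignment(mat,
                ids = paste(families$alnA$ids[pairs$seqA],
                            families$alnB$ids[pairs$seqB], sep = "::"),
                organisms = pairs$organism)
}

#' Score all candidate paralog pairings under a fitted model
#'
#' For every organism and every (A-paralog, B-paralog) combination in it,
#' sums the zero-sum-gauged inter-family couplings along the two sequences:
#' `sum over (i in A, j in B) of J_ij(a_i, b_j)`. Higher scores mean the
#' pairing is more consistent with the current co-evolutionary model.
#'
#' @param model a `coevo_potts` fitted on the concatenated matched MSA
#'   (`L = L_A + L_B` columns).
#' @param families a `coevo_paired`.
#' @return Tibble: `organism`, `seqA`, `seqB`, `score`.
#' @export
score_candidate_pairs <- function(model, families) {
  stopifnot(inherits(model, "coevo_potts"), inherits(families, "coevo_paired"))
  LA <- families$alnA$L
  LB <- families$alnB$L
  if (model$L != LA + LB) abort("model length must equal L_A + L_B")
  Jg <- zero_sum_gauge(model)$J
  inter_i <- rep(seq_len(LA), times = LB)
  inter_j <- rep(seq.int(LA + 1L, LA + LB), each = LA)
  purrr::pmap_dfr(families$index, function(organism, idxA, idxB) {
    combos <- expand.grid(seqA = idxA, seqB = idxB)
    scores <- vapply(seq_len(nrow(combos)), function(k) {
      a <- families$alnA$matrix[combos$seqA[k], ]
      b <- families$alnB$matrix[combos$seqB[k], ]
      sum(Jg[cbind(a[inter_i], b[inter_j - LA], inter_i, inter_j)])
    }, numeric(1))
    tibble(organism = organism, seqA = combos$seqA, seqB = combos$seqB,
           score = scores)
  })
}

# Greedy one-to-one selection: walk candidates by descending score (ties by
# organism, seqA, seqB) and accept until n_take pairs are matched, never
# reusing a sequence within its organism.
greedy_select <- function(candidates, n_take) {
  cand <- dplyr::arrange(candidates, dplyr::desc(.data$score),
                         .data$organism, .data$seqA, .data$seqB)
  usedA <- character(0)
  usedB <- character(0)
  take <- logical(nrow(cand))
  n_got <- 0L
  for (k in seq_len(nrow(cand))) {
    keyA <- paste(cand$organism[k], cand$seqA[k])
    keyB <- paste(cand$organism[k], cand$seqB[k])
    if (keyA %in% usedA || keyB %in% usedB) next
    take[k] <- TRUE
    usedA <- c(usedA, keyA)
    usedB <- c(usedB, keyB)
    n_got <- n_got + 1L
    if (n_got >= n_take) break
  }
  cand[take, c("organism", "seqA", "seqB", "score")]
}

#' One Iterative Paralog Matching run
#'
#' Iteration 0 fits the mean-field model on a random within-organism
#' matching; each subsequent iteration scores all candidate pairs, greedily
#' keeps the top `n_select` under the one-to-one-per-organism constraint,
#' refits, and grows `n_select` by `n_increment`. The random seed matching
#' is discarded after the first iteration. Terminates when `n_select`
#' reaches `n_max`, returning the fully matched MSA.
#'
#' @param families a `coevo_paired`.
#' @param config an [ipa_config()]. The caller controls the RNG state
#'   (`set.seed`); [acceptance_frequencies()] spawns per-run seeds itself.
#' @return A `coevo_ipa_run`: list with `pairs` (final matching tibble),
#'   `alignment` (concatenated matched MSA), `history` (tibble: iteration,
#'   n_select, n_matched).
#' @export
ipa_run <- function(families, config = ipa_config()) {
  stopifnot(inherits(families, "coevo_paired"),
            inherits(config, "coevo_ipa_config"))
  nmax <- n_max(families)
  if (nmax < 1L) abort("no shared organisms: cannot start IPA")
  pairs <- seed_matching(families)
  model <- fit_mean_field(concat_matched(families, pairs),
                          pseudocount = config$pseudocount)
  history <- tibble(iteration = 0L, n_select = nrow(pairs),
                    n_matched = nrow(pairs))
  n_select <- config$n_increment
  iteration <- 0L
  repeat {
    iteration <- iteration + 1L
    candidates <- score_candidate_pairs(model, families)
    pairs <- greedy_select(candidates, min(n_select, nmax))
    history <- dplyr::bind_rows(history,
      tibble(iteration = iteration, n_select = min(n_select, nmax),
             n_matched = nrow(pairs)))
    if (n_select >= nmax) break
    model <- fit_mean_field(concat_matched(families, pairs),
                            pseudocount = config$pseudocount)
    n_select <- n_select + config$n_increment
  }
  structure(list(pairs = pairs, alignment = concat_matched(families, pairs),
                 history = history, n_max = nmax),
            class = "coevo_ipa_run")
}

#' @export
print.coevo_ipa_run <- function(x, ...) {
  cat(sprintf("<coevo_ipa_run> %d matched pairs (n_max = %d) after %d iterations\n",
              nrow(x$pairs), x$n_max, max(x$history$iteration)))
  invisible(x)
}

#' @export
tidy.coevo_ipa_run <- function(x, ...) x$pairs

#' Fraction of a known true matching recovered by an IPA run
#'
#' @param run a `coevo_ipa_run`.
#' @param truth tibble with columns `organism`, `seqA`, `seqB` (the planted
#'   pairing, e.g. from [generate_paired_families()]).
#' @return Fraction of true pairs present in the final matching.
#' @export
matching_accuracy <- function(run, truth) {
  key <- function(d) paste(d$organism, d$seqA, d$seqB)
  mean(key(truth) %in% key(run$pairs))
}

#' Acceptance frequencies over repeated IPA runs
#'
#' Repeats the full IPA procedure `n_runs` times from distinct random seed
#' matchings. For each run, a pseudo-likelihood model is fitted on the final
#' matched MSA, inter-family scores are computed (gap-excluded Frobenius,
#' asymmetric APC, depth normalization), and every inter pair with
#' normalized score strictly above `score_threshold` is marked accepted.
#' Pairs accepted in many independent runs are the robust predictions.
#'
#' @param families a `coevo_paired`.
#' @param config an [ipa_config()]; `config$rng_seed` spawns one child seed
#'   per run, making the whole ensemble reproducible.
#' @return A `coevo_acceptance`: tibble `table` with one row per inter pair
#'   accepted at least once (`i`: family-A column, `j`: family-B column in
#'   concatenated coordinates, `count`, `frequency`, `mean_score`), plus
#'   `n_runs` and the per-run matching tibbles in `runs`.
#' @export
acceptance_frequencies <- function(families, config = ipa_config()) {
  stopifnot(inherits(families, "coevo_paired"),
            inherits(config, "coevo_ipa_config"))
  LA <- families$alnA$L
  L <- LA + families$alnB$L
  counts <- matrix(0L, LA, L - LA)
  score_sum <- matrix(0, LA, L - LA)
  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    set.seed(config$rng_seed + r - 1L)
    run <- ipa_run(families, config)
    runs[[r]] <- run$pairs
    aln <- run$alignment
    w <- compute_weights(aln, config$identity_threshold)
    model <- fit_plm(aln, w, config$fit)
    sc <- frobenius_scores(model, exclude_gap = TRUE, partition = LA)
    sc <- apc_correct_asymmetric(sc)
    sc <- normalized_inter_score(sc, n = aln$L, n_eff = w$n_eff)
    inter <- sc$S[seq_len(LA), seq.int(LA + 1L, L), drop = FALSE]
    counts <- counts + (inter > config$score_threshold)
    score_sum <- score_sum + inter
  }
  idx <- which(counts > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    inform("no inter pair was accepted in any run")
  }
  table <- tibble(i = idx[, "row"], j = idx[, "col"] + LA,
                  count = counts[idx],
                  frequency = counts[idx] / config$n_runs,
                  mean_score = score_sum[idx] / config$n_runs) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$i, .data$j)
  structure(list(table = table, n_runs = config$n_runs, partition = LA,
                 runs = runs),
            class = "coevo_acceptance")
}

#' @export
print.coevo_acceptance <- function(x, ...) {
  cat(sprintf("<coevo_acceptance> %d inter pairs accepted at least once in %d runs\n",
              nrow(x$table), x$n_runs))
  print(utils::head(x$table, 5))
  invisible(x)
}

#' @export
tidy.coevo_acceptance <- function(x, ...) x$table

#' @export
glance.coevo_acceptance <- function(x, ...) {
  tibble(n_runs = x$n_runs, n_accepted_pairs = nrow(x$table),
         max_frequency = if (nrow(x$table) > 0) max(x$table$frequency) else 0)
}
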