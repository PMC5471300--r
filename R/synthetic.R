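# Synthetic ground truth for end-to-end benchmarking: planted contact
# topologies realized as self-avoiding 3D bead chains, Potts models with
# couplings only on planted contacts, Gibbs-sampled alignments, toy PDB
# files, and paired paralog families with a known true matching.
#
# All generators consume the R RNG: wrap calls in set.seed() for
# reproducibility.

#' Generate a planted contact topology with 3D coordinates
#'
#' Builds a self-avoiding bead chain (one bead per residue, 3.8 angstrom
#' steps, 3.4 angstrom hard core) with a tunable attraction toward the
#' running centroid, and rejects chains until at least `n_long_range`
#' residue pairs with `j - i >= 5` fall within the contact cutoff. The
#' realized chain's exact contact list is the planted topology.
#'
#' @param L chain length (>= 10).
#' @param n_long_range target number of long-range (`j - i >= 5`) contacts.
#' @param cutoff contact cutoff in angstrom (default 8.5).
#' @param compactness strength of the centroid attraction (default 0.3);
#'   larger values give denser chains and more long-range contacts.
#' @param max_tries chain-level rejection budget (default 200).
#' @return A `coevo_topology`: list with `L`, `coords` (L x 3), `contacts`
#'   (tibble i, j of ALL realized contacts), `long_range` (subset with
#'   `j - i >= 5`), `cutoff`.
#' @export
generate_topology <- function(L, n_long_range, cutoff = 8.5,
                              compactness = 0.3, max_tries = 200L) {
  stopifnot(L >= 10, n_long_range >= 0)
  best <- NULL
  best_n <- -1L
  for (try in seq_len(max_tries)) {
    coords <- grow_chain(L, compactness)
    if (is.null(coords)) next
    cts <- chain_contacts(coords, cutoff)
    n_lr <- sum(cts$j - cts$i >= 5L)
    if (n_lr > best_n) {
      best <- list(coords = coords, contacts = cts)
      best_n <- n_lr
    }
    if (n_lr >= n_long_range) break
  }
  if (is.null(best)) abort("failed to grow a self-avoiding chain")
  if (best_n < n_long_range) {
    warn(sprintf(
      "rejection budget exhausted: realized %d long-range contacts (target %d)",
      best_n, n_long_range))
  }
  contacts <- best$contacts
  structure(list(L = L, coords = best$coords, contacts = contacts,
                 long_range = contacts[contacts$j - contacts$i >= 5L, ],
                 cutoff = cutoff),
            class = "coevo_topology")
}

grow_chain <- function(L, compactness, step = 3.8, hard_core = 3.4) {
  coords <- matrix(NA_real_, L, 3)
  coords[1, ] <- c(0, 0, 0)
  for (i in seq.int(2L, L)) {
    centroid <- colMeans(coords[seq_len(i - 1L), , drop = FALSE])
    placed <- FALSE
    for (attempt in seq_len(60L)) {
      dir <- stats::rnorm(3)
      pull <- centroid - coords[i - 1L, ]
      pull_n <- sqrt(sum(pull^2))
      if (pull_n > 1e-9) dir <- dir + compactness * pull / pull_n
      dir <- dir / sqrt(sum(dir^2))
      cand <- coords[i - 1L, ] + step * dir
      prev <- coords[seq_len(i - 2L), , drop = FALSE]
      if (nrow(prev) == 0L ||
          min(sqrt(rowSums((prev - rep(cand, each = nrow(prev)))^2))) >= hard_core) {
        coords[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  coords
}

chain_contacts <- function(coords, cutoff) {
  d <- as.matrix(stats::dist(coords))
  idx <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  tibble(i = as.integer(unname(idx[, "row"])),
         j = as.integer(unname(idx[, "col"]))) |>
    dplyr::arrange(.data$i, .data$j)
}

#' @export
print.coevo_topology <- function(x, ...) {
  cat(sprintf("<coevo_topology> L = %d, %d contacts (%d long-range), cutoff %.1f A\n",
              x$L, nrow(x$contacts), nrow(x$long_range), x$cutoff))
  invisible(x)
}

# Random coupling pattern on the non-gap block: entries +/- strength on a
# random subset of state pairs, then zero-sum gauged over the full block.
random_coupling_block <- function(strength, q = N_STATES, density = 0.25) {
  K <- matrix(0, q, q)
  ng <- q - 1L
  mask <- matrix(stats::runif(ng * ng) < density, ng, ng)
  signs <- matrix(sample(c(-1, 1), ng * ng, replace = TRUE), ng, ng)
  K[seq_len(ng), seq_len(ng)] <- strength * signs * mask
  double_center(K)
}

#' Plant a Potts model on a contact topology
#'
#' Zero fields; each long-range planted contact receives a random
#' `+/- strength` coupling pattern on a random subset of non-gap state pairs
#' (zero-sum gauged); all other couplings are zero. Chain-neighbor contacts
#' are geometric necessities of the bead chain and carry no coupling.
#'
#' @param topology a `coevo_topology`.
#' @param strength coupling magnitude (> 0).
#' @param density fraction of non-gap state pairs carrying coupling mass
#'   (default 0.25).
#' @return A `coevo_potts` with q = 21.
#' @export
plant_potts <- function(topology, strength = 1, density = 0.25) {
  stopifnot(inherits(topology, "coevo_topology"), strength > 0)
  L <- topology$L
  q <- N_STATES
  J <- array(0, dim = c(q, q, L, L))
  for (k in seq_len(nrow(topology$long_range))) {
    i <- topology$long_range$i[k]
    j <- topology$long_range$j[k]
    K <- random_coupling_block(strength, q, density)
    J[, , i, j] <- K
    J[, , j, i] <- t(K)
  }
  new_potts(matrix(0, L, q), J, check = FALSE)
}

#' Gibbs-sample an alignment from a Potts model
#'
#' Single-chain single-site Gibbs sampling from the model distribution:
#' `burn_in` sweeps are discarded, then one sequence is recorded every
#' `thinning` sweeps.
#'
#' @param model a `coevo_potts`.
#' @param n number of sequences.
#' @param burn_in discarded sweeps (default 200).
#' @param thinning sweeps between recorded sequences (default 5).
#' @param organisms optional per-sequence organism labels.
#' @return A `coevo_alignment` (only meaningful for q = 21 models; for
#'   reduced-alphabet models the raw integer matrix is attached unchecked).
#' @export
sample_sequences <- function(model, n, burn_in = 200L, thinning = 5L,
                             organisms = NULL) {
  stopifnot(inherits(model, "coevo_potts"), n >= 1)
  X <- cpp_gibbs_sample(model$h, as.numeric(model$J), n, burn_in, thinning)
  if (model$q == N_STATES) {
    new_alignment(X, organisms = organisms)
  } else {
    structure(list(matrix = X, ids = paste0("seq", seq_len(n)),
                   organisms = organisms %||% rep("", n),
                   M = n, L = model$L),
              class = "coevo_alignment")
  }
}

#' Write a toy single-chain PDB file
#'
#' One C-alpha-like heavy atom per residue, chain A, residues numbered
#' 1..L. Readable by [read_structure()] and any standard PDB parser.
#'
#' @param coords L x 3 coordinate matrix (angstrom).
#' @param path output path.
#' @param sequence optional one-letter residue string (length L); defaults
#'   to poly-alanine.
#' @return `path`, invisibly.
#' @export
write_toy_structure <- function(coords, path, sequence = NULL) {
  stopifnot(is.matrix(coords), ncol(coords) == 3)
  L <- nrow(coords)
  three <- setNames(names(AA3_TO_1)[seq_len(20)], unname(AA3_TO_1[seq_len(20)]))
  res3 <- if (is.null(sequence)) rep("ALA", L) else {
    stopifnot(nchar(sequence) == L)
    unname(three[strsplit(toupper(sequence), "")[[1]]])
  }
  res3[is.na(res3)] <- "ALA"
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(L), res3, seq_len(L), coords[, 1], coords[, 2], coords[, 3])
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Generate two paired paralog families with a known true matching
#'
#' Samples joint A+B sequences from a Potts model whose couplings sit on
#' planted inter-family contact pairs: each planted pair (i in A, j in B)
#' couples states through a random permutation pattern, so the state at j
#' strongly tracks the state at i in truly interacting pairs. Every organism
#' receives `min(N_A, N_B)` jointly sampled true pairs; excess paralogs on
#' the larger side are decoys whose sampled partner is discarded.
#'
#' @param n_organisms number of synthetic organisms (default 20).
#' @param paralog_range inclusive (min, max) paralog count per family per
#'   organism (default c(2, 3)).
#' @param L_A,L_B family column counts (default 20 each).
#' @param n_inter planted inter-family contact pairs (default 40, the
#'   order of magnitude of residue pairs within 8.5 angstrom across a real
#'   protein-protein interface).
#' @param strength inter coupling magnitude (default 5, which makes the
#'   partner state track the planted permutation with probability ~0.85;
#'   0 gives independent families, the negative control).
#' @param burn_in Gibbs burn-in per draw (default 300). Unlike
#'   [sample_sequences()], every joint draw comes from its own freshly
#'   burnt-in chain: organisms are independent, and at strong couplings a
#'   single thinned chain would leak state between consecutive draws.
#' @return List with `families` (a `coevo_paired`), `truth` (tibble:
#'   organism, seqA, seqB), `inter_pairs` (tibble i, j in concatenated
#'   coordinates), and `model` (the joint `coevo_potts`).
#' @export
generate_paired_families <- function(n_organisms = 20L, paralog_range = c(2L, 3L),
                                     L_A = 20L, L_B = 20L, n_inter = 40L,
                                     strength = 5, burn_in = 300L) {
  stopifnot(n_organisms >= 2, paralog_range[1] >= 1,
            paralog_range[2] >= paralog_range[1], n_inter >= 1)
  L <- L_A + L_B
  q <- N_STATES
  stopifnot(n_inter <= L_A * L_B)
  cell <- sample.int(L_A * L_B, n_inter)
  inter_pairs <- tibble(
    i = (cell - 1L) %% L_A + 1L,
    j = L_A + (cell - 1L) %/% L_A + 1L
  ) |> dplyr::arrange(.data$i, .data$j)
  J <- array(0, dim = c(q, q, L, L))
  ng <- q - 1L
  for (k in seq_len(nrow(inter_pairs))) {
    K <- matrix(0, q, q)
    perm <- sample.int(ng)
    if (strength > 0) K[cbind(seq_len(ng), perm)] <- strength
    K <- double_center(K)
    i <- inter_pairs$i[k]; j <- inter_pairs$j[k]
    J[, , i, j] <- K
    J[, , j, i] <- t(K)
  }
  model <- new_potts(matrix(0, L, q), J, check = FALSE)
  kA <- sample.int(paralog_range[2] - paralog_range[1] + 1L, n_organisms,
                   replace = TRUE) + paralog_range[1] - 1L
  kB <- sample.int(paralog_range[2] - paralog_range[1] + 1L, n_organisms,
                   replace = TRUE) + paralog_range[1] - 1L
  n_draws <- sum(pmax(kA, kB))
  Jnum <- as.numeric(model$J)
  joint <- do.call(rbind, lapply(seq_len(n_draws), function(d) {
    cpp_gibbs_sample(model$h, Jnum, 1L, burn_in, 1L)
  }))
  org_names <- sprintf("org%03d", seq_len(n_organisms))
  rowsA <- list(); rowsB <- list()
  idsA <- character(0); idsB <- character(0)
  orgA <- character(0); orgB <- character(0)
  truth <- NULL
  cursor <- 0L
  for (o in seq_len(n_organisms)) {
    n_true <- min(kA[o], kB[o])
    draws <- joint[cursor + seq_len(max(kA[o], kB[o])), , drop = FALSE]
    cursor <- cursor + max(kA[o], kB[o])
    # true pairs: joint draws 1..n_true; decoys: remaining draws, one side only
    a_rows <- draws[seq_len(kA[o]), seq_len(L_A), drop = FALSE]
    b_rows <- draws[seq_len(kB[o]), L_A + seq_len(L_B), drop = FALSE]
    idA0 <- length(idsA)
    idB0 <- length(idsB)
    rowsA[[o]] <- a_rows
    rowsB[[o]] <- b_rows
    idsA <- c(idsA, sprintf("A_%s_p%d", org_names[o], seq_len(kA[o])))
    idsB <- c(idsB, sprintf("B_%s_p%d", org_names[o], seq_len(kB[o])))
    orgA <- c(orgA, rep(org_names[o], kA[o]))
    orgB <- c(orgB, rep(org_names[o], kB[o]))
    truth <- dplyr::bind_rows(truth,
      tibble(organism = org_names[o],
             seqA = idA0 + seq_len(n_true),
             seqB = idB0 + seq_len(n_true)))
  }
  alnA <- new_alignment(do.call(rbind, rowsA), ids = idsA, organisms = orgA)
  alnB <- new_alignment(do.call(rbind, rowsB), ids = idsB, organisms = orgB)
  list(families = paired_families(alnA, alnB), truth = truth,
       inter_pairs = inter_pairs, model = model)
}
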