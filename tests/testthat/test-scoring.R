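test_that("Frobenius scores: null model, gap exclusion, closed form", {
  q <- 21L
  zero <- new_potts(matrix(0, 3, q), array(0, dim = c(q, q, 3, 3)))
  expect_true(all(frobenius_scores(zero)$S[upper.tri(diag(3))] == 0))
  # coupling mass confined to the gap row/column scores zero when excluded
  J <- array(0, dim = c(q, q, 2, 2))
  J[21, , 1, 2] <- 1; J[, 21, 1, 2] <- 1
  J[, , 2, 1] <- t(J[, , 1, 2])
  m <- new_potts(matrix(0, 2, q), J)
  expect_equal(frobenius_scores(m, exclude_gap = TRUE)$S[1, 2], 0)
  expect_gt(frobenius_scores(m, exclude_gap = FALSE)$S[1, 2], 0)
  # single non-gap entry 2: zero-sum projection on the 20-block gives
  # 2 * (1 - 1/20) = 1.9
  J2 <- array(0, dim = c(q, q, 2, 2))
  J2[1, 1, 1, 2] <- 2; J2[1, 1, 2, 1] <- 2
  m2 <- new_potts(matrix(0, 2, q), J2)
  expect_equal(frobenius_scores(m2, exclude_gap = TRUE)$S[1, 2], 1.9)
  # symmetry for random models
  set.seed(21)
  S <- frobenius_scores(random_potts(5))$S
  expect_equal(S, t(S))
})

test_that("APC: constants vanish, 4x4 toy matches hand arithmetic, homogeneity", {
  Sc <- matrix(3, 4, 4)
  out <- apc_correct(score_from_matrix(Sc))
  expect_true(all(out$S[upper.tri(out$S)] == 0))
  # entries {12:3, 13:1, 14:1, 23:1, 24:1, 34:3}: every row mean and the
  # overall mean are 5/3, so S' = S - 5/3
  S <- sym_matrix(4, list(c(1, 2, 3), c(1, 3, 1), c(1, 4, 1),
                          c(2, 3, 1), c(2, 4, 1), c(3, 4, 3)))
  out2 <- apc_correct(score_from_matrix(S))$S
  expect_equal(out2[1, 2], 4 / 3)
  expect_equal(out2[3, 4], 4 / 3)
  expect_equal(out2[1, 3], -2 / 3)
  expect_equal(out2[2, 4], -2 / 3)
  # degree-1 homogeneity
  out3 <- apc_correct(score_from_matrix(5 * S))$S
  expect_equal(out3, 5 * out2)
  expect_error(apc_correct(apc_correct(score_from_matrix(S))), "raw")
})

test_that("asymmetric APC zeroes rank-one inter blocks and matches symmetric
           correction on block-symmetric input", {
  # A = {1,2}, B = {3,4}; inter block [[4,2],[2,1]] is rank-one, so the
  # asymmetric means reproduce it exactly and the correction is zero
  S <- sym_matrix(4, list(c(1, 3, 4), c(1, 4, 2), c(2, 3, 2), c(2, 4, 1),
                          c(1, 2, 0.5), c(3, 4, 0.7)))
  out <- apc_correct_asymmetric(score_from_matrix(S, partition = 2))
  expect_lt(max(abs(out$S[1:2, 3:4])), 1e-12)
  # intra blocks get the symmetric rule: 2x2 blocks always cancel exactly
  expect_equal(out$S[1, 2], 0.5 - 0.5)
  # constant inter block corrects to exactly zero
  set.seed(22)
  Sk <- sym_matrix(6, c(
    lapply(1:3, function(i) c(i, i + 3, 2)),
    list(c(1, 2, runif(1)), c(4, 5, runif(1)))))
  Sk[2, 5] <- Sk[5, 2] <- 2; Sk[2, 6] <- Sk[6, 2] <- 2
  Sk[3, 4] <- Sk[4, 3] <- 2; Sk[3, 5] <- Sk[5, 3] <- 2
  Sk[3, 6] <- Sk[6, 3] <- 2; Sk[1, 5] <- Sk[5, 1] <- 2
  Sk[1, 6] <- Sk[6, 1] <- 2; Sk[2, 4] <- Sk[4, 2] <- 2
  out_k <- apc_correct_asymmetric(score_from_matrix(Sk, partition = 3))
  expect_lt(max(abs(out_k$S[1:3, 4:6])), 1e-12)
})

test_that("candidate counting and retention reproduce the N = L convention", {
  # L = 109, separation >= 5: (L-5)(L-4)/2 = 5460 candidates; default
  # retention keeps L = 109 of them, about 2%
  set.seed(23)
  L <- 109L
  S <- matrix(runif(L * L), L, L); S <- (S + t(S)) / 2
  rc <- rank_contacts(score_from_matrix(S, kind = "apc"))
  expect_equal(rc$n_candidates, 5460L)
  expect_equal(rc$retained, 109L)
  expect_equal(round(100 * rc$retained / rc$n_candidates), 2)
  expect_true(all(rc$pairs$j - rc$pairs$i >= 5))
  expect_true(all(diff(rc$pairs$score) <= 0))
  # doubled retention
  rc2 <- rank_contacts(score_from_matrix(S, kind = "apc"),
                       top_n_multiplier = 2)
  expect_equal(rc2$retained, 218L)
  # no eligible pairs at L = 5
  S5 <- matrix(1, 5, 5)
  expect_equal(rank_contacts(score_from_matrix(S5, kind = "apc"))$retained, 0L)
  # candidate-count formula against brute-force enumeration
  for (L in c(6L, 17L, 40L, 200L)) {
    for (m in c(1L, 5L, 9L)) {
      Sx <- matrix(0, L, L)
      rcx <- rank_contacts(score_from_matrix(Sx, kind = "apc"),
                           min_separation = m, top_n = 0)
      brute <- sum(outer(seq_len(L), seq_len(L),
                         function(i, j) j - i >= m))
      expect_equal(rcx$n_candidates, brute)
      if (L > m) {
        expect_equal(rcx$n_candidates, (L - m) * (L - m + 1) / 2)
      }
    }
  }
})

test_that("ranking is deterministic under ties", {
  S <- matrix(1, 30, 30)
  rc <- rank_contacts(score_from_matrix(S, kind = "apc"), top_n = 10)
  expect_equal(rc$pairs$i, c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1))
  expect_equal(rc$pairs$j, 6:15)
})

test_that("inter-score normalization matches the formula and keeps ranking", {
  # inter scores {-2, 1, 4}, n = n_eff: denominator |min| * 2 = 4
  S <- matrix(0, 4, 4)
  S[1, 3] <- -2; S[1, 4] <- 1; S[2, 3] <- 4; S[2, 4] <- 0.5
  S <- S + t(S)
  sc <- score_from_matrix(S, kind = "apc", partition = 2)
  out <- normalized_inter_score(sc, n = 100, n_eff = 100)
  expect_equal(out$S[1, 3], -0.5)
  expect_equal(out$S[1, 4], 0.25)
  expect_equal(out$S[2, 3], 1.0)
  expect_equal(out$kind, "normalized")
  # ranking unchanged
  r0 <- order(sc$S[1:2, 3:4])
  r1 <- order(out$S[1:2, 3:4])
  expect_equal(r1, r0)
  # degenerate minimum
  S0 <- matrix(0, 4, 4); S0[1, 3] <- 0; S0[2, 4] <- 1; S0 <- S0 + t(S0)
  expect_error(
    normalized_inter_score(score_from_matrix(S0, "apc", partition = 2),
                           10, 10),
    "minimum")
})
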