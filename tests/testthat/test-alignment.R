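test_that("residue encoding maps canonical, gap and ambiguous characters", {
  # 20 canonical letters -> 20 distinct non-gap codes
  codes <- encode_residues("ACDEFGHIKLMNPQRSTVWY")
  expect_length(unique(codes), 20)
  expect_false(any(codes == 21L))
  # gap symbols and ambiguity codes collapse onto the gap state
  expect_equal(encode_residues("A-X"), c(codes[1], 21L, 21L))
  expect_equal(encode_residues(".-BZJXUO"), rep(21L, 8))
  # case folding
  expect_equal(encode_residues("acd"), encode_residues("ACD"))
  # unknown characters name the offender and its position
  expect_error(encode_residues("AC4D"), "'4' at position 3")
  # decode inverts encode away from degenerate letters
  expect_equal(decode_residues(encode_residues("ACD-WY")), "ACD-WY")
})

test_that("fasta reading encodes matrices and extracts organisms", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P0AC41|SDHA_ECOLI OS=Escherichia coli", "ACD-",
               ">seq2 no organism here", "ACDE"), path)
  aln <- read_msa(path, "fasta")
  expect_equal(aln$M, 2L)
  expect_equal(aln$L, 4L)
  expect_equal(aln$matrix[1, 4], 21L)
  expect_equal(sum(aln$matrix == 21L), 1L)
  # Uniprot OS= tag wins; the token-after-second-pipe rule is the fallback
  expect_equal(aln$organisms[1], "Escherichia coli")
  expect_equal(coevomap:::extract_organism("sp|P1|NAME_SPEC some description"),
               "NAME_SPEC")
  expect_equal(coevomap:::extract_organism("plainheader"), "")

  writeLines(c(">a", "ACD", ">b", "AC"), path)
  expect_error(read_msa(path, "fasta"), "differ in length")
})

test_that("stockholm i/o round-trips matrix, ids and organisms", {
  aln <- aln_from_strings(c("ACD-W", "MKLYW", "A-DFG"),
                          ids = c("s1", "s2", "s3"),
                          organisms = c("Escherichia coli", "", "Homo sapiens"))
  for (fmt in c("stockholm", "fasta")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_msa(aln, path, fmt)
    back <- read_msa(path, fmt)
    expect_identical(back$matrix, aln$matrix)
    expect_identical(back$ids, aln$ids)
    expect_identical(back$organisms, aln$organisms)
  }
  bad <- withr::local_tempfile()
  writeLines(character(0), bad)
  expect_error(read_msa(bad, "stockholm"), "empty|STOCKHOLM")
})

test_that("gap filter keeps sequences at the threshold, drops strictly above", {
  s_ok <- paste(c(rep("A", 18), "-", "-"), collapse = "")    # 2/20 = 10%
  s_bad <- paste(c(rep("A", 17), "-", "-", "-"), collapse = "") # 15%
  aln <- aln_from_strings(c(s_ok, s_bad, strrep("C", 20)))
  kept <- filter_gapped_sequences(aln, 0.10)
  expect_equal(kept$M, 2L)
  expect_equal(kept$ids, aln$ids[c(1, 3)]) # order preserved
  # no-op bounds
  gap_free <- aln_from_strings(c("ACDE", "MKLY"))
  expect_identical(filter_gapped_sequences(gap_free, 0.10)$matrix,
                   gap_free$matrix)
  expect_identical(filter_gapped_sequences(aln, 1.0)$matrix, aln$matrix)
  all_gap <- aln_from_strings(c("----", "-A--"))
  expect_error(filter_gapped_sequences(all_gap, 0.10), "every sequence")
})

test_that("identity reweighting matches hand-counted neighbourhoods", {
  # 5 identical sequences: each weight 1/5, n_eff 1
  aln <- aln_from_strings(rep("ACDEFGHIKL", 5))
  w <- compute_weights(aln, 0.90)
  expect_equal(w$w, rep(0.2, 5))
  expect_equal(w$n_eff, 1)
  # all dissimilar: weights 1
  aln2 <- aln_from_strings(c("AAAAAAAAAA", "CCCCCCCCCC", "DDDDDDDDDD"))
  w2 <- compute_weights(aln2, 0.90)
  expect_equal(w2$w, rep(1, 3))
  expect_equal(w2$n_eff, 3)
  # pair at exactly the threshold counts as similar (>= convention)
  aln3 <- aln_from_strings(c("AAAAAAAAAC", "AAAAAAAAAD", "WYWYWYWYWY"))
  w3 <- compute_weights(aln3, 0.90)
  expect_equal(w3$w, c(0.5, 0.5, 1))
  expect_equal(w3$n_eff, 2)
})

test_that("weight invariants: bounds, duplication monotonicity, equivariance", {
  set.seed(42)
  for (rep_i in 1:5) {
    aln <- random_alignment(M = 12, L = 8)
    w <- compute_weights(aln)
    expect_true(all(w$w >= 1 / aln$M - 1e-12) && all(w$w <= 1))
    expect_true(w$n_eff >= 1 && w$n_eff <= aln$M)
    # appending a duplicate cannot increase n_eff
    dup <- new_alignment(rbind(aln$matrix, aln$matrix[1, ]))
    expect_lte(compute_weights(dup)$n_eff, w$n_eff + 1e-12)
    # permuting sequences permutes weights identically
    perm <- sample.int(aln$M)
    wp <- compute_weights(new_alignment(aln$matrix[perm, , drop = FALSE]))
    expect_equal(wp$w, w$w[perm])
  }
})
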