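test_that("PDB parsing filters hydrogens, HETATM and alternate locations", {
  path <- withr::local_tempfile(fileext = ".pdb")
  atoms <- rbind(
    simple_atom(1, 0, name = "CA", element = "C"),
    simple_atom(1, 0.5, name = "HA", element = "H"),        # hydrogen: out
    simple_atom(2, 3.8, name = "CA", altloc = "A", occ = 0.4),
    simple_atom(2, 5.0, name = "CA", altloc = "B", occ = 0.6), # winner
    simple_atom(3, 7.6, name = "CA", resname = "MSE", record = "HETATM"),
    simple_atom(4, 50, name = "O", resname = "HOH", record = "HETATM")
  )
  write_pdb_lines(atoms, path)
  st <- read_structure(path, "pdb")
  expect_equal(nrow(st$residues), 3L) # water dropped, MSE kept
  expect_equal(st$residues$code, c("A", "A", "M")) # MSE read as MET
  expect_false(any(st$atoms$element == "H"))
  expect_equal(st$atoms$x[st$atoms$resno == 2], 5.0) # highest occupancy
})

test_that("multi-model files select the requested model", {
  path <- withr::local_tempfile(fileext = ".pdb")
  block <- function(xoff) {
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:2, 1:2, c(0, 3.8) + xoff, c(0, 0), c(0, 0))
  }
  writeLines(c("MODEL     1", block(0), "ENDMDL",
               "MODEL     2", block(100), "ENDMDL", "END"), path)
  st1 <- read_structure(path, "pdb", model_index = 1)
  st2 <- read_structure(path, "pdb", model_index = 2)
  expect_equal(st2$atoms$x, st1$atoms$x + 100)
  expect_error(read_structure(path, "pdb", model_index = 3), "model 3")
})

test_that("mmCIF atom_site loops parse equivalently to PDB", {
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_toy", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 0.000 0.000 0.000 1.00 1",
    "ATOM 2 C CA . GLY A 2 3.800 0.000 0.000 1.00 1",
    "ATOM 3 H HA . GLY A 2 4.000 0.000 0.000 1.00 1",
    "#"), path)
  st <- read_structure(path, "mmcif")
  expect_equal(st$residues$code, c("A", "G"))
  expect_equal(nrow(st$atoms), 2L) # hydrogen removed
  expect_equal(st$atoms$x, c(0, 3.8))
})

test_that("contact maps use strict inequality at the distance cutoff", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_lines(rbind(simple_atom(1, 0), simple_atom(2, 8.5)), path)
  st <- read_structure(path, "pdb")
  expect_false(contact_map(st, cutoff = 8.5)$adjacency[1, 2])
  write_pdb_lines(rbind(simple_atom(1, 0), simple_atom(2, 8.499)), path)
  expect_true(contact_map(read_structure(path, "pdb"), 8.5)$adjacency[1, 2])
  # three residues at x = 0, 10, 14: only (2,3) within 8.5
  write_pdb_lines(rbind(simple_atom(1, 0), simple_atom(2, 10),
                        simple_atom(3, 14)), path)
  cm <- contact_map(read_structure(path, "pdb"), 8.5)
  expect_equal(tidy(cm), tibble::tibble(i = 2L, j = 3L))
  # lowering the cutoff never adds contacts
  cm_small <- contact_map(read_structure(path, "pdb"), 4.5)
  expect_true(all(cm$adjacency | !cm_small$adjacency))
})

test_that("column-residue mapping handles identity, truncation, junk", {
  m <- map_columns("ACDEFGHIKL", "ACDEFGHIKL")
  expect_equal(m$pairs$column, 1:10)
  expect_equal(m$pairs$residue, 1:10)
  expect_equal(m$coverage, 1)
  # structure missing 5 N-terminal residues: offset mapping
  m2 <- map_columns("ACDEFGHIKLMNPQRSTVWY", "GHIKLMNPQRSTVWY")
  expect_equal(m2$coverage, 15 / 20)
  expect_equal(m2$pairs$column, 6:20)
  expect_equal(m2$pairs$residue, 1:15)
  # unrelated sequences are flagged
  expect_warning(m3 <- map_columns(strrep("AC", 20), strrep("W", 11)),
                 "unreliable")
  expect_false(m3$reliable)
})

test_that("TPR curves match hand counts and handle unmappable pairs", {
  adj <- matrix(FALSE, 10, 10)
  adj[1, 6] <- adj[6, 1] <- TRUE
  adj[3, 9] <- adj[9, 3] <- TRUE
  cmap <- structure(list(residues = tibble::tibble(chain = "A", resno = 1:10,
                                                   code = "A"),
                         adjacency = adj, cutoff = 8.5, chain_pair = NULL),
                    class = "coevo_contact_map")
  mapping <- structure(list(pairs = tibble::tibble(column = 1:10,
                                                   residue = 1:10),
                            coverage = 1, reliable = TRUE),
                       class = "coevo_mapping")
  pred <- structure(list(
    pairs = tibble::tibble(i = c(1L, 2L, 3L, 4L), j = c(6L, 8L, 9L, 10L),
                           score = c(4, 3, 2, 1), rank = 1:4),
    min_separation = 5L, retained = 4L, n_candidates = 15L,
    partition = NULL), class = "coevo_contacts")
  tpr <- true_positive_rate(pred, cmap, mapping)
  expect_equal(tpr$curve$cum_tpr, c(1, 0.5, 2 / 3, 0.5))
  expect_equal(tpr$tpr, 0.5)
  # all native
  pred2 <- pred; pred2$pairs <- pred$pairs[c(1, 3), ]
  expect_true(all(true_positive_rate(pred2, cmap, mapping)$curve$cum_tpr == 1))
  # unmappable predictions are excluded and counted
  mapping5 <- mapping
  mapping5$pairs <- mapping$pairs[1:9, ] # residue 10 unmapped
  tpr5 <- true_positive_rate(pred, cmap, mapping5)
  expect_equal(tpr5$n_unmappable, 1L)
  expect_equal(nrow(tpr5$curve), 3L)
})

test_that("shortest-path classes equal the brute-force BFS oracle", {
  # chain graph 1-2, 2-3: prediction (1,3) has SP 2; disconnected gets Inf
  adj <- matrix(FALSE, 4, 4)
  adj[1, 2] <- adj[2, 1] <- TRUE
  adj[2, 3] <- adj[3, 2] <- TRUE
  cmap <- structure(list(residues = tibble::tibble(chain = "A", resno = 1:4,
                                                   code = "A"),
                         adjacency = adj, cutoff = 8.5, chain_pair = NULL),
                    class = "coevo_contact_map")
  mapping <- structure(list(pairs = tibble::tibble(column = 1:4, residue = 1:4),
                            coverage = 1, reliable = TRUE),
                       class = "coevo_mapping")
  pred <- structure(list(
    pairs = tibble::tibble(i = c(1L, 1L, 1L), j = c(2L, 3L, 4L),
                           score = c(3, 2, 1), rank = 1:3),
    min_separation = 0L, retained = 3L, n_candidates = 6L, partition = NULL),
    class = "coevo_contacts")
  sp <- shortest_path_classes(pred, cmap, mapping)
  expect_equal(sp$classes$sp, c(1, 2, Inf))
  # random toy graphs up to 50 nodes against the oracle
  set.seed(31)
  for (n in c(10L, 25L, 50L)) {
    adj <- matrix(runif(n * n) < 0.06, n, n)
    adj <- adj | t(adj)
    diag(adj) <- FALSE
    cm <- structure(list(residues = tibble::tibble(chain = "A", resno = 1:n,
                                                   code = "A"),
                         adjacency = adj, cutoff = 8.5, chain_pair = NULL),
                    class = "coevo_contact_map")
    mp <- structure(list(pairs = tibble::tibble(column = 1:n, residue = 1:n),
                         coverage = 1, reliable = TRUE),
                    class = "coevo_mapping")
    idx <- t(utils::combn(n, 2))
    sel <- idx[sample(nrow(idx), 40), , drop = FALSE]
    pr <- structure(list(
      pairs = tibble::tibble(i = sel[, 1], j = sel[, 2],
                             score = rev(seq_len(nrow(sel))),
                             rank = seq_len(nrow(sel))),
      min_separation = 0L, retained = nrow(sel), n_candidates = nrow(idx),
      partition = NULL), class = "coevo_contacts")
    got <- shortest_path_classes(pr, cm, mp)$classes$sp
    oracle <- bfs_oracle(adj)[sel]
    expect_equal(got, oracle)
  }
})
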