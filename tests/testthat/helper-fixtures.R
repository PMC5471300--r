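# Shared fixture builders. Everything is generated in code; no stored data.

# alignment from residue strings
aln_from_strings <- function(strings, ids = NULL, organisms = NULL) {
  new_alignment(do.call(rbind, lapply(strings, encode_residues)),
                ids = ids, organisms = organisms)
}

# random valid alignment
random_alignment <- function(M, L, q = 21L) {
  new_alignment(matrix(sample.int(q, M * L, replace = TRUE), M, L))
}

# a random symmetric Potts model
random_potts <- function(L, q = 21L, sd = 0.3) {
  J <- array(0, dim = c(q, q, L, L))
  if (L >= 2) {
    for (i in seq_len(L - 1L)) {
      for (j in seq.int(i + 1L, L)) {
        K <- matrix(rnorm(q * q, sd = sd), q, q)
        J[, , i, j] <- K
        J[, , j, i] <- t(K)
      }
    }
  }
  new_potts(matrix(rnorm(L * q, sd = sd), L, q), J, check = FALSE)
}

# score matrix from a symmetric matrix
score_from_matrix <- function(S, kind = "raw", partition = NULL) {
  coevomap:::new_score_matrix(S, kind, partition)
}

# symmetric matrix from the upper-triangle entries given as list(c(i,j,v))
sym_matrix <- function(n, entries) {
  S <- matrix(0, n, n)
  for (e in entries) {
    S[e[1], e[2]] <- e[3]
    S[e[2], e[1]] <- e[3]
  }
  S
}

# brute-force BFS all-pairs shortest path lengths on a boolean adjacency
# matrix; independent oracle for the graph-library route
bfs_oracle <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    depth <- 0
    seen <- rep(FALSE, n)
    seen[s] <- TRUE
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] & !seen)
        seen[nb] <- TRUE
        D[s, nb] <- depth
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
  }
  D
}

# minimal PDB writer with arbitrary atoms for parser tests:
# atoms = data.frame(record, serial, name, altloc, resname, chain, resno,
#                    x, y, z, occ, element)
write_pdb_lines <- function(atoms, path) {
  lines <- sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f  0.00          %2s",
    atoms$record, atoms$serial,
    ifelse(nchar(atoms$name) < 4, paste0(" ", atoms$name), atoms$name),
    atoms$altloc, atoms$resname, atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, atoms$occ, atoms$element)
  writeLines(c(lines, "END"), path)
  path
}

simple_atom <- function(resno, x, y = 0, z = 0, name = "CA", resname = "ALA",
                        chain = "A", record = "ATOM", altloc = " ",
                        occ = 1, element = "C", serial = resno) {
  data.frame(record = record, serial = serial, name = name, altloc = altloc,
             resname = resname, chain = chain, resno = resno,
             x = x, y = y, z = z, occ = occ, element = element,
             stringsAsFactors = FALSE)
}
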