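# Structural validation: coordinate parsing, heavy-atom contact maps,
# alignment-column <-> structure-residue mapping, true-positive-rate curves
# and shortest-path classification of predicted contacts.

AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M"
)

#' Read residue records from a structure file
#'
#' Parses PDB or mmCIF coordinates into per-atom records, keeping heavy
#' atoms only (element != H/D), resolving alternate locations to the highest
#' occupancy, and dropping HETATM residues except selenomethionine (MSE),
#' which is read as methionine.
#'
#' @param path coordinate file.
#' @param format `"pdb"` or `"mmcif"`.
#' @param model_index which model to read from multi-model files (default 1).
#' @return A `coevo_structure`: list with `atoms` (tibble: chain, resno,
#'   resname, code, atom, element, x, y, z) and `residues` (tibble: chain,
#'   resno, code), residues in file order.
#' @export
read_structure <- function(path, format = c("pdb", "mmcif"), model_index = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  atoms <- if (format == "pdb") parse_pdb(path, model_index)
           else parse_mmcif(path, model_index)
  if (nrow(atoms) == 0L) abort("no atoms selected from structure file")
  # heavy atoms only
  atoms <- dplyr::filter(atoms, !.data$element %in% c("H", "D"))
  # HETATM: drop except MSE -> MET
  atoms <- dplyr::filter(atoms, !.data$het | .data$resname == "MSE")
  atoms$resname[atoms$resname == "MSE"] <- "MET"
  if (nrow(atoms) == 0L) abort("no heavy protein atoms in selection")
  # altloc: keep the highest-occupancy location per (chain, resno, atom name)
  atoms <- atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$altloc,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  atoms <- dplyr::arrange(atoms, match(paste(atoms$chain, atoms$resno),
                                       unique(paste(atoms$chain, atoms$resno))))
  atoms$code <- unname(AA3_TO_1[atoms$resname])
  atoms$code[is.na(atoms$code)] <- "X"
  residues <- dplyr::distinct(atoms, .data$chain, .data$resno, .data$code)
  atoms <- dplyr::select(atoms, "chain", "resno", "resname", "code",
                         "atom", "element", "x", "y", "z")
  structure(list(atoms = atoms, residues = residues),
            class = "coevo_structure")
}

#' @export
print.coevo_structure <- function(x, ...) {
  cat(sprintf("<coevo_structure> %d residues, %d heavy atoms, chains: %s\n",
              nrow(x$residues), nrow(x$atoms),
              paste(unique(x$residues$chain), collapse = ", ")))
  invisible(x)
}

parse_pdb <- function(path, model_index) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 0L) {
    if (model_index > length(model_starts)) {
      abort(sprintf("model %d not present (%d models)", model_index,
                    length(model_starts)))
    }
    ends <- grep("^ENDMDL", lines)
    span <- seq.int(model_starts[model_index],
                    if (length(ends) >= model_index) ends[model_index]
                    else length(lines))
    lines <- lines[span]
  } else if (model_index != 1L) {
    abort("model_index > 1 on a single-model file")
  }
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(tibble(chain = character(), resno = integer(),
                  resname = character(), atom = character(),
                  altloc = character(), element = character(),
                  occupancy = numeric(), het = logical(),
                  x = numeric(), y = numeric(), z = numeric()))
  }
  elem <- trimws(substr(lines, 77, 78))
  name <- trimws(substr(lines, 13, 16))
  # infer element from atom name when the element column is blank
  blank <- !nzchar(elem)
  elem[blank] <- substr(gsub("[0-9]", "", name[blank]), 1, 1)
  occ <- suppressWarnings(as.numeric(substr(lines, 55, 60)))
  occ[is.na(occ)] <- 1
  tibble(
    chain = substr(lines, 22, 22),
    resno = as.integer(substr(lines, 23, 26)),
    resname = trimws(substr(lines, 18, 20)),
    atom = name,
    altloc = substr(lines, 17, 17),
    element = toupper(elem),
    occupancy = occ,
    het = substr(lines, 1, 6) == "HETATM",
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54))
  )
}

parse_mmcif <- function(path, model_index) {
  lines <- readLines(path)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (length(hdr_idx) == 0L) abort("no _atom_site loop in mmCIF file")
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body <- lines[seq.int(max(hdr_idx) + 1L, length(lines))]
  stop_at <- grep("^(#|loop_|_)", body)
  if (length(stop_at) > 0L) body <- body[seq_len(stop_at[1] - 1L)]
  body <- body[nzchar(trimws(body))]
  toks <- strsplit(trimws(body), "\\s+")
  n_bad <- sum(lengths(toks) != length(fields))
  if (n_bad > 0L) abort("malformed mmCIF atom_site rows")
  tab <- as.data.frame(do.call(rbind, toks), stringsAsFactors = FALSE)
  names(tab) <- fields
  pick <- function(...) {
    for (f in c(...)) if (f %in% fields) return(tab[[f]])
    NULL
  }
  model_no <- pick("pdbx_PDB_model_num")
  if (!is.null(model_no)) {
    models <- unique(model_no)
    if (model_index > length(models)) {
      abort(sprintf("model %d not present (%d models)", model_index,
                    length(models)))
    }
    sel <- model_no == models[model_index]
    tab <- tab[sel, , drop = FALSE]
    pick <- function(...) {
      for (f in c(...)) if (f %in% fields) return(tab[[f]])
      NULL
    }
  } else if (model_index != 1L) {
    abort("model_index > 1 on a single-model file")
  }
  clean <- function(v, default) {
    if (is.null(v)) return(default)
    v[v %in% c(".", "?")] <- NA
    v
  }
  altloc <- clean(pick("label_alt_id"), NA)
  occ <- suppressWarnings(as.numeric(clean(pick("occupancy"), NA)))
  occ[is.na(occ)] <- 1
  tibble(
    chain = pick("auth_asym_id", "label_asym_id"),
    resno = as.integer(pick("auth_seq_id", "label_seq_id")),
    resname = pick("auth_comp_id", "label_comp_id"),
    atom = gsub('"', "", pick("auth_atom_id", "label_atom_id")),
    altloc = ifelse(is.na(altloc), " ", altloc),
    element = toupper(clean(pick("type_symbol"), "")),
    occupancy = occ,
    het = pick("group_PDB") == "HETATM",
    x = as.numeric(pick("Cartn_x")),
    y = as.numeric(pick("Cartn_y")),
    z = as.numeric(pick("Cartn_z"))
  )
}

#' Heavy-atom structural contact map
#'
#' Two residues are in contact when their minimal heavy-atom distance is
#' strictly below `cutoff` (8.5 angstrom by default). Intra-chain maps
#' consider all residue pairs at sequence separation at least
#' `min_chain_separation` (default 1, i.e. all i != j); when `chain_pair` is
#' given the map is restricted to pairs crossing the two named chains.
#'
#' @param struct a `coevo_structure` from [read_structure()].
#' @param cutoff contact distance threshold in angstrom (default 8.5).
#' @param min_chain_separation minimum |i - j| along the residue order for
#'   intra-chain contacts (default 1).
#' @param chain_pair optional character vector of two chain ids for an
#'   inter-chain map.
#' @return A `coevo_contact_map`: list with `residues` (tibble), `adjacency`
#'   (boolean matrix over the residue order), `cutoff`, `chain_pair`.
#' @export
contact_map <- function(struct, cutoff = 8.5, min_chain_separation = 1L,
                        chain_pair = NULL) {
  stopifnot(inherits(struct, "coevo_structure"), cutoff > 0)
  residues <- struct$residues
  atoms <- struct$atoms
  if (!is.null(chain_pair)) {
    stopifnot(length(chain_pair) == 2L)
    residues <- dplyr::filter(residues, .data$chain %in% chain_pair)
    atoms <- dplyr::filter(atoms, .data$chain %in% chain_pair)
  }
  n <- nrow(residues)
  if (n == 0L) abort("empty chain selection")
  res_key <- paste(residues$chain, residues$resno)
  atom_res <- match(paste(atoms$chain, atoms$resno), res_key)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * tcrossprod(xyz)
  d2[d2 < 0] <- 0
  # minimal atom-atom distance per residue pair
  min_d2 <- matrix(Inf, n, n)
  grp <- split(seq_len(nrow(atoms)), atom_res)
  gi <- as.integer(names(grp))
  for (a in seq_along(grp)) {
    for (b in seq_along(grp)) {
      if (gi[b] < gi[a]) next
      min_d2[gi[a], gi[b]] <- min(d2[grp[[a]], grp[[b]]])
      min_d2[gi[b], gi[a]] <- min_d2[gi[a], gi[b]]
    }
  }
  adj <- sqrt(min_d2) < cutoff
  diag(adj) <- FALSE
  if (is.null(chain_pair)) {
    if (min_chain_separation > 1L) {
      sep <- abs(outer(seq_len(n), seq_len(n), `-`))
      adj[sep < min_chain_separation] <- FALSE
    }
  } else {
    same <- outer(residues$chain, residues$chain, `==`)
    adj[same] <- FALSE
  }
  structure(list(residues = residues, adjacency = adj, cutoff = cutoff,
                 chain_pair = chain_pair),
            class = "coevo_contact_map")
}

#' @export
print.coevo_contact_map <- function(x, ...) {
  cat(sprintf("<coevo_contact_map> %d residues, %d contacts, cutoff %.2f A\n",
              nrow(x$residues), sum(x$adjacency) / 2, x$cutoff))
  invisible(x)
}

#' @export
tidy.coevo_contact_map <- function(x, ...) {
  idx <- which(x$adjacency & upper.tri(x$adjacency), arr.ind = TRUE)
  tibble(i = as.integer(unname(idx[, "row"])),
         j = as.integer(unname(idx[, "col"]))) |>
    dplyr::arrange(.data$i, .data$j)
}

#' Map alignment columns to structure residues
#'
#' Globally aligns the family consensus sequence against the structure's
#' residue sequence (match +1, mismatch 0, affine gaps) and records the
#' aligned column/residue pairs. Coverage below 30% flags the mapping as
#' unreliable.
#'
#' @param aln_consensus consensus residue string (one character per
#'   alignment column).
#' @param structure_sequence one-letter residue string of the structure, in
#'   residue order.
#' @return A `coevo_mapping`: tibble `pairs` (column, residue), `coverage`,
#'   `reliable`.
#' @export
map_columns <- function(aln_consensus, structure_sequence) {
  stopifnot(nzchar(aln_consensus), nzchar(structure_sequence))
  alphabet <- c(AA_LETTERS, "X")
  submat <- matrix(0, length(alphabet), length(alphabet),
                   dimnames = list(alphabet, alphabet))
  diag(submat) <- 1
  submat["X", "X"] <- 0
  pa <- Biostrings::pairwiseAlignment(
    pattern = gsub("[^A-Z]", "X", toupper(aln_consensus)),
    subject = gsub("[^A-Z]", "X", toupper(structure_sequence)),
    type = "global", substitutionMatrix = submat,
    gapOpening = 5, gapExtension = 0.5)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  col_i <- cumsum(ap != "-")
  res_i <- cumsum(as != "-")
  both <- ap != "-" & as != "-"
  pairs <- tibble(column = col_i[both], residue = res_i[both])
  coverage <- nrow(pairs) / nchar(aln_consensus)
  n_match <- sum(ap[both] == as[both])
  identity <- if (nrow(pairs) > 0) n_match / nrow(pairs) else 0
  reliable <- coverage >= 0.30 && identity >= 0.30
  if (!reliable) {
    warn(sprintf(
      "column-residue mapping covers %.0f%% of columns at %.0f%% identity; %s",
      100 * coverage, 100 * identity,
      "treat structural validation as unreliable"))
  }
  structure(list(pairs = pairs, coverage = coverage, identity = identity,
                 reliable = reliable),
            class = "coevo_mapping")
}

#' @export
print.coevo_mapping <- function(x, ...) {
  cat(sprintf("<coevo_mapping> %d mapped columns, coverage %.2f%s\n",
              nrow(x$pairs), x$coverage,
              if (x$reliable) "" else " (UNRELIABLE)"))
  invisible(x)
}

# Map predicted pairs (alignment columns) onto residue indices of a contact
# map. Returns the prediction tibble with residue columns and a mapped flag.
map_prediction_pairs <- function(prediction, mapping) {
  stopifnot(inherits(prediction, "coevo_contacts"),
            inherits(mapping, "coevo_mapping"))
  lut <- setNames(mapping$pairs$residue, mapping$pairs$column)
  pr <- prediction$pairs
  pr$res_i <- unname(lut[as.character(pr$i)])
  pr$res_j <- unname(lut[as.character(pr$j)])
  pr$mapped <- !is.na(pr$res_i) & !is.na(pr$res_j)
  pr
}

#' True-positive rate of predicted contacts against a structure
#'
#' Maps each retained prediction onto the structural contact map and reports
#' the fraction of the first k mappable predictions that are native contacts
#' (the normalized frequency of reference-matching predictions), together
#' with the full cumulative curve over ranks. Unmappable pairs are excluded
#' from the denominator and counted separately.
#'
#' @param prediction a `coevo_contacts`.
#' @param map a `coevo_contact_map`.
#' @param mapping a `coevo_mapping` from [map_columns()].
#' @param top_k evaluate the TPR at this rank (default: all mappable
#'   predictions).
#' @return A `coevo_tpr`: list with `tpr`, `top_k`, `n_unmappable`, and
#'   `curve` (tibble: rank, i, j, score, native, cum_tpr).
#' @export
true_positive_rate <- function(prediction, map, mapping, top_k = NULL) {
  pr <- map_prediction_pairs(prediction, mapping)
  n_unmappable <- sum(!pr$mapped)
  pr <- pr[pr$mapped, , drop = FALSE]
  if (nrow(pr) == 0L) abort("no predictions are mappable onto the structure")
  pr$native <- map$adjacency[cbind(pr$res_i, pr$res_j)]
  pr$rank <- seq_len(nrow(pr))
  pr$cum_tpr <- cumsum(pr$native) / pr$rank
  if (is.null(top_k)) {
    top_k <- nrow(pr)
  } else if (top_k > nrow(pr)) {
    inform(sprintf("top_k = %d exceeds the %d mappable predictions; %s",
                   top_k, nrow(pr), "evaluating at the full list"))
    top_k <- nrow(pr)
  }
  curve <- tibble(rank = pr$rank, i = pr$i, j = pr$j, score = pr$score,
                  res_i = pr$res_i, res_j = pr$res_j, native = pr$native,
                  cum_tpr = pr$cum_tpr)
  structure(list(tpr = pr$cum_tpr[top_k], top_k = top_k,
                 n_unmappable = n_unmappable, curve = curve),
            class = "coevo_tpr")
}

#' @export
print.coevo_tpr <- function(x, ...) {
  cat(sprintf("<coevo_tpr> %.1f%% at rank %d (%d unmappable predictions)\n",
              100 * x$tpr, x$top_k, x$n_unmappable))
  invisible(x)
}

#' @export
tidy.coevo_tpr <- function(x, ...) x$curve

#' @export
glance.coevo_tpr <- function(x, ...) {
  tibble(tpr = x$tpr, top_k = x$top_k, n_unmappable = x$n_unmappable)
}

#' Shortest-path classification of predicted contacts
#'
#' For each predicted pair, computes the minimal number of structural-contact
#' edges needed to join the two residues in the graph of ALL structural
#' contacts (including sequence neighbors — mediation through neighbors is
#' the point of the analysis). Native contacts have SP = 1; pairs in
#' disconnected components get `Inf`.
#'
#' @inheritParams true_positive_rate
#' @return A `coevo_sp`: tibble `classes` (rank, i, j, score, sp) plus the
#'   count of unmappable predictions.
#' @export
shortest_path_classes <- function(prediction, map, mapping) {
  pr <- map_prediction_pairs(prediction, mapping)
  n_unmappable <- sum(!pr$mapped)
  pr <- pr[pr$mapped, , drop = FALSE]
  if (nrow(pr) == 0L) abort("no predictions are mappable onto the structure")
  g <- igraph::graph_from_adjacency_matrix(map$adjacency, mode = "undirected")
  d <- igraph::distances(
    g, v = unique(pr$res_i), to = unique(pr$res_j))
  sp <- d[cbind(match(pr$res_i, unique(pr$res_i)),
                match(pr$res_j, unique(pr$res_j)))]
  classes <- tibble(rank = seq_len(nrow(pr)), i = pr$i, j = pr$j,
                    score = pr$score, res_i = pr$res_i, res_j = pr$res_j,
                    sp = sp)
  structure(list(classes = classes, n_unmappable = n_unmappable),
            class = "coevo_sp")
}

#' @export
print.coevo_sp <- function(x, ...) {
  tab <- table(factor(ifelse(is.infinite(x$classes$sp), "unreachable",
                             as.character(x$classes$sp))))
  cat("<coevo_sp> SP class counts:\n")
  print(tab)
  invisible(x)
}

#' @export
tidy.coevo_sp <- function(x, ...) x$classes
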