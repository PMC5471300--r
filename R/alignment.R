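# Alignment container and MSA I/O.
#
# Sequences are stored as an integer matrix over a 21-letter alphabet:
# the 20 canonical amino acids coded 1..20 (alphabetical one-letter order)
# and the gap as code 21. Organism labels ride along one per sequence so
# that paralog matching can group sequences by genome.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
GAP_CODE <- 21L
N_STATES <- 21L

#' Construct an alignment object
#'
#' Bundles an integer-coded MSA matrix (codes 1..21, gap = 21) with
#' per-sequence identifiers and organism labels.
#'
#' @param matrix integer matrix, M sequences x L columns, codes in 1..21.
#' @param ids character vector of sequence identifiers (length M).
#' @param organisms character vector of organism keys (length M); `""` when
#'   unknown.
#' @return An object of class `coevo_alignment` with fields `matrix`, `ids`,
#'   `organisms`, `M`, `L`.
#' @export
new_alignment <- function(matrix, ids = NULL, organisms = NULL) {
  if (!is.matrix(matrix) || nrow(matrix) < 1L || ncol(matrix) < 1L) {
    abort("alignment matrix must have at least one sequence and one column")
  }
  storage.mode(matrix) <- "integer"
  if (anyNA(matrix) || any(matrix < 1L) || any(matrix > N_STATES)) {
    abort(sprintf("alignment codes must lie in 1..%d", N_STATES))
  }
  m <- nrow(matrix)
  if (is.null(ids)) ids <- paste0("seq", seq_len(m))
  if (is.null(organisms)) organisms <- rep("", m)
  stopifnot(length(ids) == m, length(organisms) == m)
  structure(
    list(matrix = unname(matrix), ids = as.character(ids),
         organisms = as.character(organisms), M = m, L = ncol(matrix)),
    class = "coevo_alignment"
  )
}

#' @export
print.coevo_alignment <- function(x, ...) {
  cat(sprintf("<coevo_alignment> %d sequences x %d columns\n", x$M, x$L))
  n_org <- sum(nzchar(x$organisms))
  if (n_org > 0) {
    cat(sprintf("  organisms labelled: %d (%d distinct)\n", n_org,
                length(unique(x$organisms[nzchar(x$organisms)]))))
  }
  invisible(x)
}

#' Encode amino-acid residues as integer codes
#'
#' Maps the 20 canonical amino acids to codes 1..20 (alphabetical one-letter
#' order) and `-`/`.` to the gap code 21. Ambiguous or nonstandard letters
#' (B, Z, J, X, U, O) also map to the gap code, the convention for
#' Uniprot-derived alignments. Lowercase is folded to uppercase.
#'
#' @param residues a character string of residues.
#' @return Integer vector of codes in 1..21.
#' @examples
#' encode_residues("ACD-")
#' @export
encode_residues <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1L)
  chars <- toupper(strsplit(residues, "")[[1]])
  codes <- match(chars, AA_LETTERS)
  is_gap <- chars %in% c("-", ".", "B", "Z", "J", "X", "U", "O")
  codes[is_gap] <- GAP_CODE
  bad <- which(is.na(codes))
  if (length(bad) > 0L) {
    abort(sprintf("cannot encode character '%s' at position %d",
                  chars[bad[1]], bad[1]))
  }
  codes
}

#' Decode integer codes back to residue characters
#'
#' @param codes integer vector of codes in 1..21.
#' @param gap_char character used for the gap code (default `-`).
#' @return A single character string.
#' @export
decode_residues <- function(codes, gap_char = "-") {
  stopifnot(all(codes >= 1L), all(codes <= N_STATES))
  paste(c(AA_LETTERS, gap_char)[codes], collapse = "")
}

# Uniprot-style organism extraction: the "OS=" tag when present, else the
# token after the second '|', else "".
extract_organism <- function(header) {
  m <- regmatches(header, regexpr("OS=.*?(?= [A-Za-z]{2}=|$)", header, perl = TRUE))
  if (length(m) == 1L) return(sub("^OS=", "", m))
  parts <- strsplit(header, "|", fixed = TRUE)[[1]]
  if (length(parts) >= 3L) return(strsplit(parts[3], "[ \t]")[[1]][1])
  ""
}

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or Stockholm file and encodes it over the 21-letter
#' alphabet. Organism labels are taken from a Uniprot `OS=` header tag, from a
#' Stockholm `#=GS <id> OS <organism>` annotation, or from the token after the
#' second `|` of the identifier; otherwise left empty.
#'
#' @param path path to the alignment file.
#' @param format `"fasta"` or `"stockholm"`.
#' @return A [new_alignment()] object.
#' @export
read_msa <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (format == "fasta") {
    seqs <- Biostrings::readAAStringSet(path)
    if (length(seqs) == 0L) abort("empty alignment file")
    headers <- names(seqs)
    strings <- as.character(seqs)
    ids <- vapply(strsplit(headers, "[ \t]"), `[`, character(1), 1)
    organisms <- vapply(headers, extract_organism, character(1), USE.NAMES = FALSE)
  } else {
    sto <- parse_stockholm(path)
    strings <- sto$seqs
    ids <- sto$ids
    organisms <- sto$organisms
  }
  lens <- nchar(strings)
  if (length(unique(lens)) != 1L) {
    abort(sprintf("aligned sequences differ in length (%d .. %d)",
                  min(lens), max(lens)))
  }
  mat <- do.call(rbind, lapply(strings, encode_residues))
  new_alignment(mat, ids = ids, organisms = organisms)
}

parse_stockholm <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) abort("empty alignment file")
  if (!grepl("^# STOCKHOLM", lines[1])) {
    abort("not a Stockholm file (missing '# STOCKHOLM 1.0' header)")
  }
  seqs <- list()
  organisms <- list()
  for (ln in lines[-1]) {
    if (grepl("^//", ln) || !nzchar(trimws(ln))) next
    if (grepl("^#=GS\\s", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) >= 4L && f[3] == "OS") {
        organisms[[f[2]]] <- paste(f[-(1:3)], collapse = " ")
      }
      next
    }
    if (grepl("^#", ln)) next
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) != 2L) abort(sprintf("malformed Stockholm sequence line: %s", ln))
    seqs[[f[1]]] <- paste0(seqs[[f[1]]] %||% "", f[2])
  }
  if (length(seqs) == 0L) abort("empty alignment file")
  ids <- names(seqs)
  orgs <- vapply(ids, function(id) {
    organisms[[id]] %||% extract_organism(id)
  }, character(1), USE.NAMES = FALSE)
  list(ids = ids, seqs = unlist(seqs, use.names = FALSE), organisms = orgs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a multiple sequence alignment
#'
#' Inverse of [read_msa()]; gaps are emitted as `-`. In Stockholm output,
#' organism labels are written as `#=GS <id> OS <organism>` lines.
#'
#' @param aln a `coevo_alignment`.
#' @param path output path.
#' @param format `"fasta"` or `"stockholm"`.
#' @return `path`, invisibly.
#' @export
write_msa <- function(aln, path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  stopifnot(inherits(aln, "coevo_alignment"))
  strings <- apply(aln$matrix, 1L, decode_residues)
  if (format == "fasta") {
    headers <- ifelse(nzchar(aln$organisms),
                      paste0(aln$ids, " OS=", aln$organisms), aln$ids)
    out <- character(2L * aln$M)
    out[c(TRUE, FALSE)] <- paste0(">", headers)
    out[c(FALSE, TRUE)] <- strings
  } else {
    gs <- which(nzchar(aln$organisms))
    out <- c("# STOCKHOLM 1.0",
             sprintf("#=GS %s OS %s", aln$ids[gs], aln$organisms[gs]),
             sprintf("%s %s", format(aln$ids, width = max(nchar(aln$ids))), strings),
             "//")
  }
  writeLines(out, path)
  invisible(path)
}

#' Remove heavily gapped sequences
#'
#' Drops every sequence whose gap fraction exceeds `max_gap_fraction`
#' (strictly more than; a sequence exactly at the threshold is kept), the
#' standard pre-filter applied before model inference.
#'
#' @param aln a `coevo_alignment`.
#' @param max_gap_fraction maximum tolerated fraction of gapped columns per
#'   sequence (default 0.10).
#' @return The filtered `coevo_alignment`, sequence order preserved.
#' @export
filter_gapped_sequences <- function(aln, max_gap_fraction = 0.10) {
  stopifnot(inherits(aln, "coevo_alignment"),
            max_gap_fraction >= 0, max_gap_fraction <= 1)
  gap_frac <- rowMeans(aln$matrix == GAP_CODE)
  keep <- gap_frac <= max_gap_fraction
  if (!any(keep)) abort("gap filter removed every sequence")
  new_alignment(aln$matrix[keep, , drop = FALSE], aln$ids[keep],
                aln$organisms[keep])
}

#' Sequence reweighting by identity clustering
#'
#' Computes the standard DCA redundancy correction: sequence `s` receives
#' weight `1 / n_s`, where `n_s` counts the sequences (including `s` itself)
#' whose fractional identity with `s` is at least `identity_threshold`.
#' Identity is the fraction of the L columns with equal codes, the gap
#' counting as an ordinary 21st symbol. The effective number of sequences
#' `n_eff` is the sum of weights.
#'
#' @param aln a `coevo_alignment`.
#' @param identity_threshold clustering radius (default 0.90, i.e. a maximum
#'   90\% identity between effective sequences).
#' @return An object of class `coevo_weights`: list with `w` (length M) and
#'   `n_eff`.
#' @export
compute_weights <- function(aln, identity_threshold = 0.90) {
  stopifnot(inherits(aln, "coevo_alignment"),
            identity_threshold > 0, identity_threshold <= 1)
  w <- cpp_identity_weights(aln$matrix, identity_threshold)
  structure(list(w = w, n_eff = sum(w)), class = "coevo_weights")
}

#' @export
print.coevo_weights <- function(x, ...) {
  cat(sprintf("<coevo_weights> M = %d, n_eff = %.2f\n", length(x$w), x$n_eff))
  invisible(x)
}

#' Tidy an alignment into one row per sequence
#'
#' @param x a `coevo_alignment`.
#' @param ... unused.
#' @return A tibble with columns `id`, `organism`, `gap_fraction`, `sequence`.
#' @export
tidy.coevo_alignment <- function(x, ...) {
  tibble(
    id = x$ids,
    organism = x$organisms,
    gap_fraction = rowMeans(x$matrix == GAP_CODE),
    sequence = apply(x$matrix, 1L, decode_residues)
  )
}

#' One-line alignment summary
#'
#' @param x a `coevo_alignment`.
#' @param identity_threshold passed to [compute_weights()].
#' @param ... unused.
#' @return A one-row tibble with `M`, `L`, `n_eff`.
#' @export
glance.coevo_alignment <- function(x, identity_threshold = 0.90, ...) {
  tibble(M = x$M, L = x$L,
         n_eff = compute_weights(x, identity_threshold)$n_eff)
}
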