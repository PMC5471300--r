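# Workflow orchestration: the intra-family route (MSA -> DCA -> ranked
# contacts -> structural validation -> SP report) and the inter-family route
# (paired MSAs -> IPA ensemble -> acceptance table), with resolved-config
# digests and deterministic seeding.

#' Workflow configuration
#'
#' Collects every stage parameter with its standard default, plus input
#' locations and the master seed. The resolved configuration (and its hash)
#' is written next to every output, so any run can be reproduced from its
#' report directory.
#'
#' @param workflow `"intra"` or `"inter"`.
#' @param msa path to an alignment file or a `coevo_alignment` (intra).
#' @param structure optional path to a PDB/mmCIF file or a
#'   `coevo_structure` (intra validation; also optional for inter).
#' @param msa_a,msa_b paths or alignments for the two families (inter).
#' @param msa_format `"fasta"` or `"stockholm"` for path inputs.
#' @param max_gap_fraction sequence gap filter (default 0.10).
#' @param identity_threshold reweighting radius (default 0.90).
#' @param lambda L2 regularization for the pseudo-likelihood fit
#'   (default 0.01).
#' @param min_separation minimum chain separation of intra candidates
#'   (default 5).
#' @param top_n_multiplier retention scale factor (default 1; 2 doubles the
#'   retained contacts).
#' @param cutoff structural contact cutoff in angstrom (default 8.5).
#' @param pseudocount mean-field pseudocount for IPA (default 0.5).
#' @param n_increment IPA selection increment (default 6).
#' @param score_threshold IPA acceptance threshold (default 0.8).
#' @param n_runs number of IPA runs (default 10).
#' @param chain_pair optional two chain ids for inter-chain validation.
#' @param seed master seed (default 1).
#' @param out_dir optional directory for TSV reports.
#' @return A list of class `coevo_config`.
#' @export
run_config <- function(workflow = c("intra", "inter"), msa = NULL,
                       structure = NULL, msa_a = NULL, msa_b = NULL,
                       msa_format = "fasta", max_gap_fraction = 0.10,
                       identity_threshold = 0.90, lambda = 0.01,
                       min_separation = 5L, top_n_multiplier = 1,
                       cutoff = 8.5, pseudocount = 0.5, n_increment = 6L,
                       score_threshold = 0.8, n_runs = 10L,
                       chain_pair = NULL, seed = 1L, out_dir = NULL) {
  workflow <- match.arg(workflow)
  structure(
    list(workflow = workflow, msa = msa, structure = structure,
         msa_a = msa_a, msa_b = msa_b, msa_format = msa_format,
         max_gap_fraction = max_gap_fraction,
         identity_threshold = identity_threshold, lambda = lambda,
         min_separation = as.integer(min_separation),
         top_n_multiplier = top_n_multiplier, cutoff = cutoff,
         pseudocount = pseudocount, n_increment = as.integer(n_increment),
         score_threshold = score_threshold, n_runs = as.integer(n_runs),
         chain_pair = chain_pair, seed = as.integer(seed),
         out_dir = out_dir),
    class = "coevo_config")
}

config_digest <- function(config) {
  scalars <- config[!names(config) %in% c("msa", "structure", "msa_a", "msa_b",
                                          "out_dir")]
  rlang::hash(scalars)
}

resolve_alignment <- function(x, format) {
  if (inherits(x, "coevo_alignment")) x else read_msa(x, format)
}

resolve_structure <- function(x) {
  if (is.null(x) || inherits(x, "coevo_structure")) return(x)
  fmt <- if (grepl("\\.cif$", x, ignore.case = TRUE)) "mmcif" else "pdb"
  read_structure(x, fmt)
}

#' Majority-rule consensus sequence of an alignment
#'
#' Most frequent non-gap residue per column (ties broken alphabetically);
#' columns that are all-gap yield `X`.
#'
#' @param aln a `coevo_alignment`.
#' @return A character string of length L.
#' @export
consensus_sequence <- function(aln) {
  stopifnot(inherits(aln, "coevo_alignment"))
  letters_out <- vapply(seq_len(aln$L), function(i) {
    col <- aln$matrix[, i]
    col <- col[col != GAP_CODE]
    if (length(col) == 0L) return("X")
    tab <- tabulate(col, nbins = 20L)
    AA_LETTERS[which.max(tab)]
  }, character(1))
  paste(letters_out, collapse = "")
}

write_report_tsv <- function(df, path, digest) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# coevomap config digest: %s", digest), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the intra-family workflow
#'
#' Filters and reweights the MSA, fits the pseudo-likelihood Potts model,
#' ranks APC-corrected gap-excluded Frobenius scores, and — when a structure
#' is supplied — validates the retained predictions (TPR curve and
#' shortest-path classification). Logs alignment depth, effective depth and
#' filter casualty counts.
#'
#' @param config a [run_config()] with `workflow = "intra"`.
#' @return A `coevo_report`: list with `alignment`, `weights`, `model`,
#'   `scores`, `contacts`, and (with a structure) `structure_map`,
#'   `mapping`, `tpr`, `sp`; plus `log` (named list of run statistics) and
#'   `digest`.
#' @export
run_intra <- function(config) {
  stopifnot(inherits(config, "coevo_config"), config$workflow == "intra")
  set.seed(config$seed)
  digest <- config_digest(config)
  aln0 <- resolve_alignment(config$msa, config$msa_format)
  aln <- filter_gapped_sequences(aln0, config$max_gap_fraction)
  n_dropped <- aln0$M - aln$M
  w <- compute_weights(aln, config$identity_threshold)
  inform(sprintf("MSA: M = %d (dropped %d at gap filter), L = %d, n_eff = %.1f",
                 aln$M, n_dropped, aln$L, w$n_eff))
  model <- fit_plm(aln, w, fit_config(lambda_h = config$lambda,
                                      lambda_J = config$lambda,
                                      identity_threshold = config$identity_threshold))
  scores <- apc_correct(frobenius_scores(model, exclude_gap = TRUE))
  contacts <- rank_contacts(scores, min_separation = config$min_separation,
                            top_n = aln$L,
                            top_n_multiplier = config$top_n_multiplier)
  report <- list(alignment = aln, weights = w, model = model, scores = scores,
                 contacts = contacts, digest = digest,
                 log = list(M = aln$M, M_dropped = n_dropped, L = aln$L,
                            n_eff = w$n_eff, retained = contacts$retained))
  struct <- resolve_structure(config$structure)
  if (!is.null(struct)) {
    cmap <- contact_map(struct, cutoff = config$cutoff)
    mapping <- map_columns(consensus_sequence(aln),
                           paste(cmap$residues$code, collapse = ""))
    report$structure_map <- cmap
    report$mapping <- mapping
    report$tpr <- true_positive_rate(contacts, cmap, mapping)
    report$sp <- shortest_path_classes(contacts, cmap, mapping)
    report$log$tpr <- report$tpr$tpr
    report$log$unmappable <- report$tpr$n_unmappable
  }
  class(report) <- "coevo_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_tsv(tidy(contacts),
                     file.path(config$out_dir, "contacts.tsv"), digest)
    if (!is.null(struct)) {
      ann <- dplyr::left_join(tidy(report$tpr),
                              dplyr::select(tidy(report$sp), "rank", "sp"),
                              by = "rank")
      write_report_tsv(ann, file.path(config$out_dir, "validation.tsv"),
                       digest)
    }
    saveRDS_free_config(config, digest)
  }
  report
}

# The resolved config is written as JSON (text-only deliverables).
saveRDS_free_config <- function(config, digest) {
  scalars <- config[!names(config) %in% c("msa", "structure", "msa_a", "msa_b",
                                          "out_dir")]
  scalars$digest <- digest
  jsonlite::write_json(scalars, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
}

#' Run the inter-family workflow
#'
#' Builds the paired-family index from the two organism-labelled MSAs, runs
#' the IPA ensemble, and reports per-pair acceptance frequencies; when an
#' inter-chain structure is supplied, the top accepted pairs are annotated
#' against the inter-chain contact map.
#'
#' @param config a [run_config()] with `workflow = "inter"`.
#' @return A `coevo_report`: list with `families`, `acceptance`, optional
#'   `structure_map`, plus `log` and `digest`.
#' @export
run_inter <- function(config) {
  stopifnot(inherits(config, "coevo_config"), config$workflow == "inter")
  digest <- config_digest(config)
  alnA <- resolve_alignment(config$msa_a, config$msa_format)
  alnB <- resolve_alignment(config$msa_b, config$msa_format)
  alnA <- filter_gapped_sequences(alnA, config$max_gap_fraction)
  alnB <- filter_gapped_sequences(alnB, config$max_gap_fraction)
  families <- paired_families(alnA, alnB)
  if (n_max(families) < 1L) abort("no shared organisms between the families")
  ipa_cfg <- ipa_config(
    n_increment = config$n_increment, n_runs = config$n_runs,
    pseudocount = config$pseudocount,
    score_threshold = config$score_threshold,
    identity_threshold = config$identity_threshold,
    rng_seed = config$seed,
    fit = fit_config(lambda_h = config$lambda, lambda_J = config$lambda,
                     identity_threshold = config$identity_threshold))
  acceptance <- acceptance_frequencies(families, ipa_cfg)
  report <- list(families = families, acceptance = acceptance,
                 digest = digest,
                 log = list(n_max = n_max(families),
                            n_organisms = nrow(families$index),
                            n_runs = config$n_runs,
                            n_accepted = nrow(acceptance$table)))
  struct <- resolve_structure(config$structure)
  if (!is.null(struct) && !is.null(config$chain_pair)) {
    cmap <- contact_map(struct, cutoff = config$cutoff,
                        chain_pair = config$chain_pair)
    report$structure_map <- cmap
  }
  class(report) <- "coevo_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_tsv(tidy(acceptance),
                     file.path(config$out_dir, "acceptance.tsv"), digest)
    saveRDS_free_config(config, digest)
  }
  report
}

#' @export
print.coevo_report <- function(x, ...) {
  cat("<coevo_report>\n")
  for (nm in names(x$log)) {
    cat(sprintf("  %s: %s\n", nm, format(x$log[[nm]], digits = 4)))
  }
  invisible(x)
}

#' @export
glance.coevo_report <- function(x, ...) {
  tibble::as_tibble(x$log)
}
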