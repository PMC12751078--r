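#' Overlap-analysis stage
#'
#' Orchestrates harmonization outputs for a set of snapshots: the exclusive
#' (UpSet) intersection table, the overlap-coefficient matrix, per-species
#' protein counts of shared PPIs, and a JSON summary (union / full
#' intersection sizes, median coefficient). Per-stage record counts are
#' logged to stderr.
#'
#' @param snapshots Named list of at least two [ppi_snapshot] objects.
#' @param outdir Output directory (created if absent).
#' @param shared_k Sharing threshold for the species counts (default 2).
#' @param shared_mode "at_least" (default) or "exactly" databases.
#' @param top_k Species to report (default 10).
#' @return Invisible list with the computed tables.
#' @export
run_overlap <- function(snapshots, outdir, shared_k = 2L,
                        shared_mode = c("at_least", "exactly"), top_k = 10L) {
  shared_mode <- match.arg(shared_mode)
  if (length(snapshots) < 2L) stop("at least two snapshots required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (s in snapshots) {
    message(sprintf("[overlap] %s: %d records", s$name, nrow(s$records)))
  }
  sig <- exclusive_intersections(snapshots)
  mat <- overlap_matrix(snapshots)
  shared <- if (shared_mode == "at_least") {
    shared_by_at_least(snapshots, shared_k)
  } else {
    shared_by_exactly(snapshots, shared_k)
  }
  spc <- species_protein_counts(shared, top_k = top_k)
  utils::write.table(sig, file.path(outdir, "signatures.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(mat$values, file.path(outdir, "overlap_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = TRUE,
                     col.names = NA)
  utils::write.table(spc, file.path(outdir, "species_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  union_keys <- shared_by_at_least(snapshots, 1L)
  summary <- list(n_snapshots = length(snapshots),
                  union_size = length(union_keys),
                  intersection_size = length(
                    shared_by_at_least(snapshots, length(snapshots))),
                  n_shared = length(shared),
                  median_overlap = mat$median_offdiag)
  jsonlite::write_json(summary, file.path(outdir, "overlap_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(signatures = sig, matrix = mat, species_counts = spc,
                 summary = summary))
}

#' Conservation, enrichment and network stage
#'
#' Builds ortholog-group conservation spans from the snapshots, writes the
#' span histogram, the structure-coverage enrichment table (odds ratios vs
#' the non-conserved baseline), the unsolved-pairs listing and the
#' conserved-network exports (edge TSV and GraphML) with a component
#' summary.
#'
#' @param snapshots Named list of [ppi_snapshot] objects.
#' @param accession_to_group Named character vector accession -> group.
#' @param index A `structure_index`.
#' @param outdir Output directory.
#' @param min_span Network inclusion threshold (default 5).
#' @param cap Span histogram / enrichment top bin (default 6).
#' @param k_components Components to summarize (default 10).
#' @return Invisible list with spans, histogram, enrichment, unsolved,
#'   graph and component summary.
#' @export
run_conserve <- function(snapshots, accession_to_group, index, outdir,
                         min_span = 5L, cap = 6L, k_components = 10L) {
  if (is.null(accession_to_group) || length(accession_to_group) == 0L) {
    stop("missing mapping table: accession_to_group")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  spans <- build_spans(snapshots, accession_to_group)
  message(sprintf("[conserve] %d group pairs (%d records unmapped)",
                  nrow(spans), attr(spans, "n_unmapped")))
  write_spans(spans, file.path(outdir, "spans.tsv"))
  hist <- span_histogram(spans, cap)
  utils::write.table(data.frame(span = names(hist), n = as.integer(hist)),
                     file.path(outdir, "span_histogram.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sharing <- species_pair_sharing(spans)
  utils::write.table(sharing, file.path(outdir, "species_sharing.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  db_counts <- conserved_counts_by_database(spans, min_span = 2L)
  utils::write.table(data.frame(database = names(db_counts),
                                n_conserved = as.integer(db_counts)),
                     file.path(outdir, "conserved_by_database.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  enr <- enrichment_table(spans, index, cap)
  utils::write.table(enr, file.path(outdir, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  uns <- unsolved_pairs(spans, index, min_span = 2L)
  utils::write.csv(uns, file.path(outdir, "unsolved.csv"), row.names = FALSE,
                   quote = FALSE)
  graph <- build_graph(spans, index, min_span)
  export_graph(graph, file.path(outdir, "network_edges.tsv"), "edge-tsv")
  export_graph(graph, file.path(outdir, "network.graphml"), "graphml")
  comps <- components_ranked(graph, k_components)
  comp_summary <- do.call(rbind, lapply(seq_along(comps), function(i) {
    cs <- edge_color_summary(comps[[i]])
    data.frame(rank = i, n_nodes = igraph::vcount(comps[[i]]),
               n_edges = igraph::ecount(comps[[i]]),
               n_solved = cs[["n_solved"]], n_unsolved = cs[["n_unsolved"]])
  }))
  if (is.null(comp_summary)) {
    comp_summary <- data.frame(rank = integer(), n_nodes = integer(),
                               n_edges = integer(), n_solved = integer(),
                               n_unsolved = integer())
  }
  utils::write.table(comp_summary, file.path(outdir, "components.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(spans = spans, histogram = hist, sharing = sharing,
                 enrichment = enr, unsolved = uns, graph = graph,
                 components = comp_summary))
}

#' Ensemble-analysis stage
#'
#' RMSF, inter-chain contact map and (when a reference is supplied) a
#' TM-score fold-consistency report for a structural ensemble.
#'
#' @param ensemble A `ppi_ensemble` or path to a multi-model PDB file.
#' @param outdir Output directory.
#' @param chain_a,chain_b Chains for the contact map (defaults: first two).
#' @param cutoff Contact cutoff in Angstrom (default 8).
#' @param reference Optional reference (`ppi_ensemble`, N x 3 matrix or PDB
#'   path) for TM scoring.
#' @param correspondence Optional residue correspondence for [tm_score()].
#' @param tm_threshold Fold threshold (default 0.5).
#' @param fit_selection Residues used for the RMSF fit (default all).
#' @return Invisible list with rmsf, contact map and tm report (or NULL).
#' @export
run_ensemble <- function(ensemble, outdir, chain_a = NULL, chain_b = NULL,
                         cutoff = 8, reference = NULL, correspondence = NULL,
                         tm_threshold = 0.5, fit_selection = NULL) {
  if (is.character(ensemble)) ensemble <- read_pdb_ensemble(ensemble)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  message(sprintf("[ensemble] %d models, %d residues", n_models(ensemble),
                  dim(ensemble$coords)[2L]))
  prof <- rmsf(ensemble, fit_selection)
  utils::write.table(prof, file.path(outdir, "rmsf.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cmap <- NULL
  if (length(ensemble$chains) >= 2L) {
    if (is.null(chain_a)) chain_a <- ensemble$chains[1L]
    if (is.null(chain_b)) chain_b <- ensemble$chains[2L]
    cmap <- contact_frequency(ensemble, chain_a, chain_b, cutoff)
    write_contact_map(cmap, file.path(outdir, "contact_map.tsv"))
  }
  tm_report <- NULL
  if (!is.null(reference)) {
    if (is.character(reference)) reference <- read_pdb_ensemble(reference)
    fc <- fold_consistency(ensemble, reference, correspondence, tm_threshold)
    tms <- vapply(seq_len(n_models(ensemble)), function(m) {
      tm_score(ensemble_coords(ensemble, m), reference, correspondence)$tm
    }, 0)
    tm_report <- list(threshold = tm_threshold, per_model = tms,
                      fraction_above = fc$fraction_above[1L],
                      mean_tm = fc$mean_tm[1L])
    jsonlite::write_json(tm_report, file.path(outdir, "tm_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(rmsf = prof, contact_map = cmap, tm = tm_report))
}

#' End-to-end demonstration run on synthetic data
#'
#' Generates every pipeline input with planted ground truth (database
#' snapshots with a subset relation, orthology maps with planted spans, a
#' structure index with planted odds ratios, sequence families with planted
#' clusters, a coordinate ensemble with planted flexibility), runs every
#' stage, and writes all outputs plus a `truth.json`. Fully deterministic:
#' two runs with the same seed produce byte-identical output trees.
#'
#' @param outdir Output directory.
#' @param seed Integer seed driving all generators.
#' @param scale Multiplier on problem sizes (default 1, desk scale).
#' @return Invisible list of per-stage results.
#' @export
run_demo <- function(outdir, seed = 1L, scale = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_snapshots(n_universe_pairs = as.integer(5000 * scale),
                            seed = seed)
  ov <- run_overlap(sim$snapshots, file.path(outdir, "overlap"))

  orth <- simulate_orthology(n_group_pairs = as.integer(600 * scale),
                             seed = seed)
  idx <- simulate_structure_index(build_spans(orth$snapshots,
                                              orth$accession_to_group),
                                  seed = seed)
  cons <- run_conserve(orth$snapshots, orth$accession_to_group, idx$index,
                       file.path(outdir, "conserve"), min_span = 5L)

  fam <- simulate_sequences(seed = seed)
  cl <- greedy_cluster(fam$sequences, threshold = 0.8)
  write_clusters(cl, file.path(outdir, "clusters.tsv"))

  ens <- simulate_ensemble(n_models = max(20L, as.integer(50 * scale)),
                           seed = seed)
  enres <- run_ensemble(ens$ensemble, file.path(outdir, "ensemble"),
                        fit_selection = ens$truth$core)

  truth <- list(
    seed = seed,
    snapshot_sizes = lengths(sim$truth$sets),
    subset_pair = sim$truth$db_specs[!is.na(sim$truth$db_specs$subset_of),
                                     c("name", "subset_of")],
    planted_or = idx$truth$planted_or,
    planted_p_by_level = idx$truth$p_by_level,
    n_planted_clusters = length(unique(fam$labels)),
    expected_rmsf = ens$truth$expected_rmsf,
    planted_contact = ens$truth$contact)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(overlap = ov, conserve = cons, clusters = cl,
                 ensemble = enres, truth = truth))
}
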