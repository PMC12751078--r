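# Each generator draws from its own seeded stream (seed + fixed offset) and
# restores the caller's RNG state, so changing one generator's draw count
# never perturbs another's output.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# distinct unordered pairs of `pool`, sampled uniformly without replacement
sample_distinct_pairs <- function(pool, n) {
  total <- choose(length(pool), 2)
  if (n > total) stop("pair universe too small for requested size")
  keys <- character(0)
  while (length(keys) < n) {
    i <- sample.int(length(pool), 2 * (n - length(keys)) + 16L, replace = TRUE)
    j <- sample.int(length(pool), 2 * (n - length(keys)) + 16L, replace = TRUE)
    ok <- i != j
    k <- paste(pmin(pool[i[ok]], pool[j[ok]]), pmax(pool[i[ok]], pool[j[ok]]),
               sep = "\t")
    keys <- unique(c(keys, k))
  }
  keys[seq_len(n)]
}

#' Default database specification for snapshot simulation
#'
#' Eight databases of decreasing size with one exact-subset relation (the
#' smallest database is drawn entirely from within another, emulating a
#' database that redistributes a subset of a larger resource -- its size is
#' 11% of its superset's). Sizes scale with the universe so the same shape
#' holds at any simulation scale.
#'
#' @param n_universe_pairs Universe size the sizes are scaled to.
#' @return data.frame with columns `name`, `size`, `subset_of`.
#' @export
default_db_specs <- function(n_universe_pairs = 5000L) {
  frac <- c(0.70, 0.52, 0.42, 0.32, 0.24, 0.18, 0.12)
  sizes <- pmax(1L, as.integer(round(frac * n_universe_pairs)))
  data.frame(
    name = paste0("db_", letters[1:8]),
    size = c(sizes, max(1L, as.integer(round(0.11 * sizes[3L])))),
    subset_of = c(NA, NA, NA, NA, NA, NA, NA, "db_c"),
    stringsAsFactors = FALSE)
}

#' Simulate PPI database snapshots with known overlap structure
#'
#' Draws each database's record set from a shared pair universe. Databases
#' with a `subset_of` entry are sampled from within their superset's records,
#' so the requested containment holds exactly and the overlap coefficient of
#' such a pair is 1 by construction. The truth record stores every sampled
#' key set, so every downstream overlap statistic can be computed
#' independently of the pipeline.
#'
#' @param n_universe_pairs Size of the shared pair universe.
#' @param db_specs data.frame(name, size, subset_of) as in
#'   [default_db_specs()].
#' @param n_species Number of taxa; pairs are assigned taxa with a skew
#'   emulating the concentration of curated interactions on model organisms.
#' @param n_proteins Accession pool size.
#' @param seed Integer seed.
#' @return List with `snapshots` (named list of [ppi_snapshot]) and `truth`
#'   (list: `universe`, `sets` = named key vectors, `db_specs`).
#' @export
simulate_snapshots <- function(n_universe_pairs = 5000L,
                               db_specs = default_db_specs(n_universe_pairs),
                               n_species = 10L, n_proteins = 400L,
                               seed = 1L) {
  stopifnot(all(db_specs$size >= 1L), !anyDuplicated(db_specs$name))
  for (i in seq_len(nrow(db_specs))) {
    sup <- db_specs$subset_of[i]
    if (!is.na(sup)) {
      sup_size <- db_specs$size[db_specs$name == sup]
      if (length(sup_size) != 1L) stop("subset_of refers to unknown database: ", sup)
      if (db_specs$size[i] > sup_size) {
        stop("infeasible spec: subset '", db_specs$name[i],
             "' larger than its superset '", sup, "'")
      }
    }
  }
  with_local_seed(seed + 101L, {
    pool <- sprintf("P%05d", seq_len(n_proteins))
    pair_keys <- sample_distinct_pairs(pool, n_universe_pairs)
    tax_probs <- (1 / seq_len(n_species)^1.5)
    taxid <- sample.int(n_species, n_universe_pairs, replace = TRUE,
                        prob = tax_probs / sum(tax_probs)) + 9000L
    universe <- paste(pair_keys, taxid, sep = "\t")
    sets <- list()
    for (i in order(!is.na(db_specs$subset_of))) {  # supersets first
      nm <- db_specs$name[i]
      src <- if (is.na(db_specs$subset_of[i])) universe else
        sets[[db_specs$subset_of[i]]]
      sets[[nm]] <- sample(src, db_specs$size[i])
    }
    sets <- sets[db_specs$name]
    snapshots <- lapply(names(sets), function(nm) {
      rec <- keys_to_records(sets[[nm]])
      ppi_snapshot(nm, rec$a, rec$b, rec$taxid)
    })
    names(snapshots) <- names(sets)
    list(snapshots = snapshots,
         truth = list(universe = universe, sets = sets, db_specs = db_specs))
  })
}

#' Simulate orthology-mapped interactions with planted conservation spans
#'
#' Samples a span (number of observing species) for each ortholog-group pair
#' from `span_distribution`, selects that many taxa, and emits exactly one
#' species-level accession pair per selected taxon (each group has one
#' ortholog accession per taxon). Observations are distributed over
#' databases for provenance. Recovery is exact by construction: running
#' [build_spans()] on the emitted records reproduces the planted spans.
#'
#' @param n_group_pairs Number of distinct ortholog-group pairs.
#' @param n_species Number of taxa.
#' @param span_distribution Probability vector over spans 1..length; default
#'   a decreasing distribution over spans 1..8 dominated by span 1.
#' @param n_databases Number of source databases.
#' @param seed Integer seed.
#' @return List with `snapshots`, `accession_to_group`,
#'   `accession_to_taxid` (named character vectors) and `truth_spans`
#'   (data.frame group_a, group_b, span, taxa list column).
#' @export
simulate_orthology <- function(n_group_pairs = 600L, n_species = 10L,
                               span_distribution = NULL, n_databases = 8L,
                               seed = 1L) {
  if (is.null(span_distribution)) {
    span_distribution <- c(0.50, 0.20, 0.10, 0.07, 0.05, 0.04, 0.025, 0.015)
  }
  span_distribution <- span_distribution / sum(span_distribution)
  max_span <- length(span_distribution)
  if (max_span > n_species) stop("span distribution longer than species count")
  with_local_seed(seed + 211L, {
    n_groups <- max(16L, 2L * ceiling(sqrt(n_group_pairs)))
    groups <- sprintf("%dat2759", 100000L + seq_len(n_groups))
    gp_keys <- sample_distinct_pairs(groups, n_group_pairs)
    gp <- keys_to_records(paste(gp_keys, 0L, sep = "\t"))[, c("a", "b")]
    spans <- sample.int(max_span, n_group_pairs, replace = TRUE,
                        prob = span_distribution)
    taxids <- 9000L + seq_len(n_species)
    dbs <- paste0("db_", letters[seq_len(n_databases)])
    acc_counter <- 0L
    acc_of <- new.env(parent = emptyenv())
    get_acc <- function(group, tax) {
      key <- paste(group, tax)
      if (!is.null(acc_of[[key]])) return(acc_of[[key]])
      acc_counter <<- acc_counter + 1L
      acc <- sprintf("P%05d", acc_counter)
      acc_of[[key]] <- acc
      acc
    }
    rec_a <- rec_b <- rec_db <- character(0)
    rec_tax <- integer(0)
    taxa_list <- vector("list", n_group_pairs)
    for (i in seq_len(n_group_pairs)) {
      tx <- sort(sample(taxids, spans[i]))
      taxa_list[[i]] <- tx
      for (t in tx) {
        a <- get_acc(gp$a[i], t)
        b <- get_acc(gp$b[i], t)
        hit_dbs <- sample(dbs, sample.int(min(3L, n_databases), 1L))
        rec_a <- c(rec_a, rep(a, length(hit_dbs)))
        rec_b <- c(rec_b, rep(b, length(hit_dbs)))
        rec_tax <- c(rec_tax, rep(t, length(hit_dbs)))
        rec_db <- c(rec_db, hit_dbs)
      }
    }
    keys <- ls(acc_of)
    acc <- vapply(keys, function(k) acc_of[[k]], "")
    parts <- strsplit(keys, " ", fixed = TRUE)
    accession_to_group <- stats::setNames(vapply(parts, `[[`, "", 1L), acc)
    accession_to_taxid <- stats::setNames(vapply(parts, `[[`, "", 2L), acc)
    snapshots <- lapply(dbs, function(d) {
      sel <- rec_db == d
      ppi_snapshot(d, rec_a[sel], rec_b[sel], rec_tax[sel])
    })
    names(snapshots) <- dbs
    truth <- data.frame(group_a = pmin(gp$a, gp$b),
                        group_b = pmax(gp$a, gp$b),
                        span = spans, stringsAsFactors = FALSE)
    truth$taxa <- taxa_list
    truth <- truth[order(truth$group_a, truth$group_b), , drop = FALSE]
    rownames(truth) <- NULL
    list(snapshots = snapshots, accession_to_group = accession_to_group,
         accession_to_taxid = accession_to_taxid, truth_spans = truth)
  })
}

#' Synthetic spans with exact per-level counts
#'
#' Builds a `ppi_spans` object with exactly `n_per_level` group pairs at
#' each span level 1..`n_levels`, for calibration studies where the span
#' composition must be controlled exactly.
#'
#' @param n_per_level Group pairs per span level.
#' @param n_levels Number of span levels.
#' @return A `ppi_spans` object (sources empty).
#' @export
make_level_spans <- function(n_per_level, n_levels) {
  n <- n_per_level * n_levels
  ids <- sprintf("%dat2759", 200000L + seq_len(2L * n))
  out <- data.frame(group_a = ids[seq_len(n) * 2L - 1L],
                    group_b = ids[seq_len(n) * 2L],
                    span = rep(seq_len(n_levels), each = n_per_level),
                    stringsAsFactors = FALSE)
  out$taxa <- lapply(out$span, function(s) 9000L + seq_len(s))
  out$sources <- rep(list(character(0)), n)
  attr(out, "n_unmapped") <- 0L
  class(out) <- c("ppi_spans", "data.frame")
  out
}

#' Simulate a structure index with planted per-span odds ratios
#'
#' Each group pair is marked solved with probability p(level) where
#' odds(p) = planted_or[level] x odds(baseline_rate); levels beyond the last
#' planted value reuse it. Solved pairs receive synthetic 4-character PDB
#' IDs. The truth record carries the implied per-level probabilities.
#'
#' @param spans A `ppi_spans` object.
#' @param baseline_rate Solved probability at span 1, in (0, 1).
#' @param planted_or Odds ratios per span level starting at level 1 (which
#'   must be 1 by definition); default c(1, 6, 22, 80).
#' @param seed Integer seed.
#' @return List with `index` (a `structure_index`) and `truth` (list:
#'   `p_by_level`, `planted_or`, `solved_keys`).
#' @export
simulate_structure_index <- function(spans, baseline_rate = 0.05,
                                     planted_or = c(1, 6, 22, 80),
                                     seed = 1L) {
  stopifnot(inherits(spans, "ppi_spans"),
            baseline_rate > 0, baseline_rate < 1,
            planted_or[1] == 1, all(planted_or > 0), all(is.finite(planted_or)))
  base_odds <- baseline_rate / (1 - baseline_rate)
  odds <- base_odds * planted_or
  p_by_level <- odds / (1 + odds)
  if (any(p_by_level >= 1)) stop("implied solved probability >= 1")
  with_local_seed(seed + 307L, {
    lvl <- pmin(spans$span, length(planted_or))
    solved <- stats::runif(nrow(spans)) < p_by_level[lvl]
    n_solved <- sum(solved)
    pdb <- paste0(sample(1:9, n_solved, replace = TRUE),
                  vapply(seq_len(n_solved), function(i) {
                    paste(sample(c(LETTERS, 0:9), 3L, replace = TRUE),
                          collapse = "")
                  }, ""))
    index <- structure_index(spans$group_a[solved], spans$group_b[solved], pdb)
    list(index = index,
         truth = list(p_by_level = p_by_level, planted_or = planted_or,
                      solved_keys = span_key(spans)[solved]))
  })
}

#' Simulate sequence families with planted cluster structure
#'
#' Cluster centroids are i.i.d. uniform amino-acid sequences; the first
#' member of each family is the unmutated centroid (the family founder,
#' mirroring the centroid convention of greedy clusterers) and every further
#' member is the centroid with per-site substitution probability
#' `divergence` (substituted sites receive a uniformly drawn *different*
#' residue).
#'
#' @param n_clusters Number of planted clusters.
#' @param members_per_cluster Members per cluster (the first being the
#'   centroid itself).
#' @param divergence Per-site substitution probability in [0, 0.5).
#' @param length Sequence length.
#' @param seed Integer seed.
#' @return List with `sequences` (named accession -> sequence) and `labels`
#'   (named integer cluster labels).
#' @export
simulate_sequences <- function(n_clusters = 3L, members_per_cluster = 40L,
                               divergence = 0.1, length = 120L, seed = 1L) {
  stopifnot(divergence >= 0, divergence < 0.5)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  with_local_seed(seed + 401L, {
    seqs <- character(0)
    labels <- integer(0)
    for (k in seq_len(n_clusters)) {
      centroid <- sample(aa, length, replace = TRUE)
      for (j in seq_len(members_per_cluster)) {
        s <- centroid
        mut <- if (j == 1L) integer() else which(stats::runif(length) < divergence)
        if (length(mut)) {
          s[mut] <- vapply(s[mut], function(x) sample(setdiff(aa, x), 1L), "")
        }
        seqs <- c(seqs, paste(s, collapse = ""))
        labels <- c(labels, k)
      }
    }
    acc <- sprintf("S%04d", seq_along(seqs))
    list(sequences = stats::setNames(seqs, acc),
         labels = stats::setNames(labels, acc))
  })
}

#' Simulate a two-chain C-alpha ensemble with planted flexibility
#'
#' Two chains are placed as rigid bodies (C-alpha spacing 3.8 Angstrom,
#' inter-chain separation well beyond the contact cutoff). Per model, each
#' residue is displaced by an isotropic Gaussian with the residue's planted
#' amplitude (0 on the rigid core), so the expected RMSF of residue i is
#' amplitude_i x sqrt(3). A designated interface residue pair is placed
#' within contact distance in exactly `round(frac x n_models)` models and
#' far outside it otherwise, deterministically, so the recovered contact
#' frequency is exact.
#'
#' @param n_models Number of conformations (>= 2).
#' @param n_res_a,n_res_b Residues in chains A and B.
#' @param amplitude Per-residue displacement amplitudes (length
#'   n_res_a + n_res_b); default: rigid core with a flexible C-terminal
#'   stretch on chain A ramping to 1.5 Angstrom.
#' @param contact List(res_a, res_b, frac, near, far): chain-local residue
#'   indices of the planted interface pair, occupancy fraction, and the
#'   near/far separations in Angstrom; default plants the pair at the chain
#'   midpoints with 30% occupancy.
#' @param seed Integer seed.
#' @return List with `ensemble` (a `ppi_ensemble`) and `truth` (list:
#'   `amplitude`, `expected_rmsf` = amplitude x sqrt(3), `NA` at the
#'   deterministically placed interface residue, `core` residue indices,
#'   `contact`).
#' @export
simulate_ensemble <- function(n_models = 200L, n_res_a = 60L, n_res_b = 40L,
                              amplitude = NULL, contact = NULL,
                              seed = 1L) {
  stopifnot(n_models >= 2L)
  if (is.null(contact)) {
    contact <- list(res_a = max(1L, n_res_a %/% 2L),
                    res_b = max(1L, n_res_b %/% 2L),
                    frac = 0.3, near = 5, far = 30)
  }
  stopifnot(contact$res_a >= 1L, contact$res_a <= n_res_a,
            contact$res_b >= 1L, contact$res_b <= n_res_b)
  n <- n_res_a + n_res_b
  if (is.null(amplitude)) {
    amplitude <- numeric(n)
    flex <- seq(max(1L, n_res_a - 15L), n_res_a)
    amplitude[flex] <- seq(0.2, 1.5, length.out = length(flex))
  }
  stopifnot(length(amplitude) == n, all(amplitude >= 0))
  jb_global <- n_res_a + contact$res_b
  amplitude[jb_global] <- 0      # interface residue is placed deterministically
  amplitude[contact$res_a] <- 0
  base <- rbind(
    cbind(3.8 * seq_len(n_res_a), 0, 0),
    cbind(3.8 * seq_len(n_res_b), 20, 0))
  with_local_seed(seed + 503L, {
    n_contact <- round(contact$frac * n_models)
    contact_models <- sort(sample.int(n_models, n_contact))
    coords <- array(0, dim = c(n_models, n, 3L))
    for (m in seq_len(n_models)) {
      xyz <- base
      for (i in which(amplitude > 0)) {
        xyz[i, ] <- xyz[i, ] + stats::rnorm(3L, 0, amplitude[i])
      }
      sep <- if (m %in% contact_models) contact$near else contact$far
      xyz[jb_global, ] <- base[contact$res_a, ] + c(0, sep, 0)
      coords[m, , ] <- xyz
    }
    ens <- new_ensemble(chain = rep(c("A", "B"), c(n_res_a, n_res_b)),
                        resno = c(seq_len(n_res_a), seq_len(n_res_b)),
                        coords = coords)
    expected_rmsf <- amplitude * sqrt(3)
    # the interface residue is positioned by the contact plant, not by the
    # Gaussian profile; its fluctuation is bimodal, so it is excluded from
    # the planted RMSF profile
    expected_rmsf[jb_global] <- NA_real_
    list(ensemble = ens,
         truth = list(amplitude = amplitude,
                      expected_rmsf = expected_rmsf,
                      core = which(amplitude == 0 &
                                     seq_len(n) != jb_global),
                      contact = c(contact,
                                  list(frac_exact = n_contact / n_models))))
  })
}

#' Write a minimal 15-column PSI-MITAB file for a snapshot
#'
#' Reader-testing helper: emits the minimal MITAB 2.5 dialect the package
#' reads back (uniprotkb IDs, taxid columns, a psi-mi interaction-type
#' column), not the full 42-column format.
#'
#' @param snapshot A [ppi_snapshot].
#' @param path Output path.
#' @param interaction_type MI identifier written in column 12.
#' @return `path`, invisibly.
#' @export
write_mitab <- function(snapshot, path, interaction_type = "MI:0915") {
  rec <- snapshot$records
  line <- sprintf(paste0(
    "uniprotkb:%s\tuniprotkb:%s\t-\t-\t-\t-\t-\t-\t-\t",
    "taxid:%d\ttaxid:%d\tpsi-mi:\"%s\"(type)\t-\t-\t-"),
    rec$a, rec$b, rec$taxid, rec$taxid, interaction_type)
  writeLines(line, path)
  invisible(path)
}
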