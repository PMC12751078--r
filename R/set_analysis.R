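#' Exclusive (UpSet-style) intersections of snapshots
#'
#' Partitions the union of all record keys by exact membership signature:
#' every key is assigned to exactly one signature, the full set of snapshots
#' that contain it, so signature counts sum to the union size. This is the
#' quantity shown as UpSet intersection bars. Snapshot display order is
#' fixed by descending snapshot size (ties broken by name).
#'
#' @param snapshots List of [ppi_snapshot] objects (or a named list of key
#'   vectors). Names must be unique.
#' @return data.frame with columns `signature` (snapshot names joined by
#'   `&` in display order), `degree` (number of snapshots) and `count`,
#'   sorted by count descending.
#' @export
exclusive_intersections <- function(snapshots) {
  sets <- .key_sets(snapshots)
  if (length(sets) < 1L) stop("at least one snapshot required")
  ord <- order(-lengths(sets), names(sets))
  sets <- sets[ord]
  universe <- unique(unlist(sets, use.names = FALSE))
  if (length(universe) == 0L) {
    return(data.frame(signature = character(), degree = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe))
  sig <- apply(member, 1L, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  tab <- table(sig)
  out <- data.frame(signature = names(tab),
                    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$signature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keys shared by at least k snapshots
#'
#' `k = 1` returns the union, `k = n` the full intersection. The result is
#' antitone in `k`.
#'
#' @param snapshots List of [ppi_snapshot] objects or named key vectors.
#' @param k Minimum number of snapshots a key must appear in.
#' @return Character vector of record keys (sorted).
#' @export
shared_by_at_least <- function(snapshots, k) {
  sets <- .key_sets(snapshots)
  if (length(k) != 1L || is.na(k) || k < 1L || k > length(sets)) {
    stop("k must be between 1 and the number of snapshots")
  }
  counts <- table(unlist(lapply(sets, unique), use.names = FALSE))
  sort(names(counts)[counts >= k])
}

#' Keys shared by exactly k snapshots
#'
#' Companion to [shared_by_at_least()] for analyses that read "found in two
#' out of eight databases" as exactly-two rather than at-least-two.
#'
#' @inheritParams shared_by_at_least
#' @return Character vector of record keys (sorted).
#' @export
shared_by_exactly <- function(snapshots, k) {
  sets <- .key_sets(snapshots)
  if (length(k) != 1L || is.na(k) || k < 1L || k > length(sets)) {
    stop("k must be between 1 and the number of snapshots")
  }
  counts <- table(unlist(lapply(sets, unique), use.names = FALSE))
  sort(names(counts)[counts == k])
}

#' Szymkiewicz-Simpson overlap coefficient of two snapshots
#'
#' |A intersect B| / min(|A|, |B|). Symmetric, in [0, 1], and equal to 1
#' whenever either set contains the other -- which is why a database that is
#' a strict subset of another scores 1 even though their sizes differ.
#' An empty set yields `NA` (a coefficient of 0 would fabricate
#' disagreement).
#'
#' @param A,B [ppi_snapshot] objects or key vectors.
#' @return Fraction in [0, 1], or `NA_real_` if either set is empty.
#' @export
overlap_coefficient <- function(A, B) {
  a <- unique(if (inherits(A, "ppi_snapshot")) snapshot_keys(A) else as.character(A))
  b <- unique(if (inherits(B, "ppi_snapshot")) snapshot_keys(B) else as.character(B))
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Pairwise overlap-coefficient matrix
#'
#' Computes [overlap_coefficient()] for every unordered snapshot pair.
#' `median_offdiag` is the median over the strict upper triangle (each
#' database pair counted once; ties use the midpoint convention), with
#' empty-set `NA` entries excluded.
#'
#' @param snapshots List of at least two [ppi_snapshot] objects or named
#'   key vectors.
#' @return An object of class `overlap_matrix`: list with `values`
#'   (symmetric matrix, unit diagonal for non-empty sets) and
#'   `median_offdiag`.
#' @export
overlap_matrix <- function(snapshots) {
  sets <- .key_sets(snapshots)
  if (length(sets) < 2L) stop("at least two snapshots required")
  ord <- order(-lengths(sets), names(sets))
  sets <- lapply(sets[ord], unique)
  n <- length(sets)
  vals <- matrix(NA_real_, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) {
    vals[i, i] <- if (length(sets[[i]]) > 0L) 1 else NA_real_
    if (i < n) for (j in seq(i + 1L, n)) {
      vals[i, j] <- vals[j, i] <- overlap_coefficient(sets[[i]], sets[[j]])
    }
  }
  upper <- vals[upper.tri(vals)]
  structure(list(values = vals,
                 median_offdiag = stats::median(upper, na.rm = TRUE)),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("Overlap-coefficient matrix (%d snapshots), median off-diagonal %.3f\n",
              nrow(x$values), x$median_offdiag))
  print(round(x$values, 3))
  invisible(x)
}

#' Maximum entrywise change between two overlap matrices
#'
#' Used to quantify how much identifier harmonization (e.g. homology
#' clustering) moves the between-database overlap coefficients; reported as
#' a percentage over off-diagonal entries.
#'
#' @param before,after `overlap_matrix` objects over the same snapshot names.
#' @return Maximum absolute off-diagonal difference, in percent.
#' @export
overlap_delta <- function(before, after) {
  stopifnot(inherits(before, "overlap_matrix"), inherits(after, "overlap_matrix"))
  if (!identical(dimnames(before$values), dimnames(after$values))) {
    stop("overlap matrices have mismatched snapshot names")
  }
  off <- !diag(nrow(before$values))
  100 * max(abs(after$values[off] - before$values[off]), na.rm = TRUE)
}

#' Unique-protein counts per species for a set of shared PPIs
#'
#' For interactions found in multiple databases, counts the distinct
#' accessions per taxid (a protein in a self-pair counts once), reported in
#' descending order.
#'
#' @param shared_keys Character record keys (from [shared_by_at_least()]) or
#'   a records data.frame with columns a, b, taxid.
#' @param top_k Number of species to keep; `Inf` keeps all.
#' @return data.frame with columns `taxid` and `n_proteins`, sorted
#'   descending by count.
#' @export
species_protein_counts <- function(shared_keys, top_k = 10L) {
  rec <- if (is.character(shared_keys)) keys_to_records(shared_keys) else shared_keys
  if (nrow(rec) == 0L) {
    return(data.frame(taxid = integer(), n_proteins = integer()))
  }
  long <- data.frame(taxid = rep(rec$taxid, 2L), acc = c(rec$a, rec$b),
                     stringsAsFactors = FALSE)
  long <- long[!duplicated(paste(long$taxid, long$acc)), , drop = FALSE]
  tab <- table(long$taxid)
  out <- data.frame(taxid = as.integer(names(tab)),
                    n_proteins = as.integer(tab))
  out <- out[order(-out$n_proteins, out$taxid), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}
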