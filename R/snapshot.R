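#' Canonical ordering of an unordered protein pair
#'
#' All set operations in the package identify an interaction by its
#' *unordered* accession pair. `canonical_pair()` returns the pair sorted
#' lexicographically so that (A, B) and (B, A) collapse to one identity.
#' Self-pairs (homodimers) are permitted and returned unchanged.
#'
#' @param a,b Character vectors of accessions (recycled to common length).
#' @return For scalar input, a character vector of length 2; for vector
#'   input, a two-column character matrix with columns `a` and `b`.
#' @examples
#' canonical_pair("Q2", "Q1")   # c("Q1", "Q2")
#' canonical_pair("P1", "P1")   # self-pair kept
#' @export
canonical_pair <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) != length(b)) {
    n <- max(length(a), length(b))
    a <- rep_len(a, n)
    b <- rep_len(b, n)
  }
  if (any(is.na(a) | is.na(b) | !nzchar(a) | !nzchar(b))) {
    stop("accessions must be non-empty strings")
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  if (length(a) == 1L) {
    return(c(lo, hi))
  }
  cbind(a = lo, b = hi)
}

#' Number of possible unordered protein pairs
#'
#' The combinatorial ceiling on unique one-to-one interactions in a proteome
#' of `n` proteins: choose(n, 2) = n(n-1)/2. For proteome sizes of roughly
#' 4,000 (E. coli) and 20,000 (human) this evaluates to about 8 million and
#' 200 million potential pairs.
#'
#' @param n_proteins Non-negative integer vector.
#' @return Numeric vector of exact pair counts.
#' @examples
#' n_possible_pairs(4000)    # 7,998,000
#' n_possible_pairs(20000)   # 199,990,000
#' @export
n_possible_pairs <- function(n_proteins) {
  n <- as.numeric(n_proteins)
  if (any(is.na(n)) || any(n < 0) || any(n != floor(n))) {
    stop("n_proteins must be non-negative integers")
  }
  n * (n - 1) / 2
}

#' Construct a PPI snapshot
#'
#' A snapshot is one database release reduced to a set of canonical
#' interaction records keyed by (pair, taxid). Pairs are canonicalized and
#' duplicate keys collapsed at construction.
#'
#' @param name Snapshot (database) label.
#' @param a,b Accession vectors of the two interaction partners.
#' @param taxid Integer NCBI taxonomy IDs (recycled).
#' @param stats Optional named list of ingestion counters
#'   (n_read, n_malformed, n_filtered, n_cross_species, n_no_taxid).
#' @return An object of class `ppi_snapshot` with fields `name` and
#'   `records` (data.frame with columns a, b, taxid).
#' @export
ppi_snapshot <- function(name, a = character(), b = character(),
                         taxid = integer(), stats = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  a <- as.character(a)
  b <- as.character(b)
  taxid <- rep_len(as.integer(taxid), length(a))
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) > 0L) {
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    key <- paste(lo, hi, taxid, sep = "\t")
    keep <- !duplicated(key)
    rec <- data.frame(a = lo[keep], b = hi[keep], taxid = taxid[keep],
                      stringsAsFactors = FALSE)
    rec <- rec[order(rec$a, rec$b, rec$taxid), , drop = FALSE]
    rownames(rec) <- NULL
  } else {
    rec <- data.frame(a = character(), b = character(), taxid = integer(),
                      stringsAsFactors = FALSE)
  }
  structure(list(name = name, records = rec, stats = stats),
            class = "ppi_snapshot")
}

#' Record keys of a snapshot
#'
#' The comparison key used throughout the set analysis is
#' (canonical pair, taxid): the same accession pair observed in two species
#' counts as two distinct PPIs.
#'
#' @param x A `ppi_snapshot` or a records data.frame with columns a, b, taxid.
#' @return Character vector of tab-joined keys.
#' @export
snapshot_keys <- function(x) {
  rec <- if (inherits(x, "ppi_snapshot")) x$records else x
  if (nrow(rec) == 0L) return(character())
  paste(rec$a, rec$b, rec$taxid, sep = "\t")
}

#' Reconstruct records from keys
#'
#' @param keys Character keys as produced by [snapshot_keys()].
#' @return data.frame with columns a, b, taxid.
#' @export
keys_to_records <- function(keys) {
  if (length(keys) == 0L) {
    return(data.frame(a = character(), b = character(), taxid = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "\t", fixed = TRUE)
  data.frame(a = vapply(parts, `[[`, "", 1L),
             b = vapply(parts, `[[`, "", 2L),
             taxid = as.integer(vapply(parts, `[[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' @export
print.ppi_snapshot <- function(x, ...) {
  cat(sprintf("PPI snapshot '%s': %d records, %d taxa\n",
              x$name, nrow(x$records),
              length(unique(x$records$taxid))))
  if (length(x$stats)) {
    cat("  ingestion:",
        paste(names(x$stats), unlist(x$stats), sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

# internal: coerce a list of snapshots to a named list of key sets
.key_sets <- function(snapshots) {
  if (inherits(snapshots, "ppi_snapshot")) snapshots <- list(snapshots)
  nm <- vapply(snapshots, function(s) {
    if (inherits(s, "ppi_snapshot")) s$name else NA_character_
  }, "")
  if (anyNA(nm)) nm <- names(snapshots)
  if (is.null(nm) || anyNA(nm) || any(!nzchar(nm))) {
    stop("snapshots must be ppi_snapshot objects or a named list")
  }
  if (anyDuplicated(nm)) stop("duplicate snapshot names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  sets <- lapply(snapshots, function(s) {
    if (inherits(s, "ppi_snapshot")) snapshot_keys(s) else as.character(s)
  })
  names(sets) <- nm
  sets
}
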