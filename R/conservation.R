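#' Map an interaction to a canonical ortholog-group pair
#'
#' Both accessions are looked up in the accession-to-group table; if either
#' is unmapped the record yields `NULL`. Homodimers whose partners share one
#' group give a self group-pair (g, g).
#'
#' @param a,b Accessions of the interaction partners.
#' @param accession_to_group Named character vector accession -> group ID.
#' @return Character vector of length 2 (canonical order), or `NULL`.
#' @export
to_group_pair <- function(a, b, accession_to_group) {
  ga <- accession_to_group[a]
  gb <- accession_to_group[b]
  if (is.na(ga) || is.na(gb)) return(NULL)
  canonical_pair(unname(ga), unname(gb))
}

#' Build cross-species conservation spans
#'
#' Projects every interaction record onto its ortholog-group pair and
#' aggregates, per distinct group pair, the set of taxa and the set of
#' source databases in which it was observed. The *span* of a group pair is
#' the number of distinct taxa -- interactions sharing the same ortholog-group
#' pair in two or more species are the evolutionarily conserved ones.
#' Within-species paralog pairs mapping to the same group pair do not
#' inflate the span (taxa form a set), and database of origin is provenance
#' only.
#'
#' @param snapshots List of [ppi_snapshot] objects.
#' @param accession_to_group Named character vector accession -> group ID.
#' @return An object of class `ppi_spans`: data.frame with columns
#'   `group_a`, `group_b`, `span`, plus list columns `taxa` and `sources`;
#'   attribute `n_unmapped` counts records dropped for an unmapped partner.
#' @export
build_spans <- function(snapshots, accession_to_group) {
  if (inherits(snapshots, "ppi_snapshot")) snapshots <- list(snapshots)
  recs <- do.call(rbind, lapply(snapshots, function(s) {
    stopifnot(inherits(s, "ppi_snapshot"))
    if (nrow(s$records) == 0L) return(NULL)
    cbind(s$records, source = s$name, stringsAsFactors = FALSE)
  }))
  if (is.null(recs) || nrow(recs) == 0L) {
    return(empty_spans(0L))
  }
  ga <- unname(accession_to_group[recs$a])
  gb <- unname(accession_to_group[recs$b])
  mapped <- !is.na(ga) & !is.na(gb)
  n_unmapped <- sum(!mapped)
  recs <- recs[mapped, , drop = FALSE]
  ga <- ga[mapped]; gb <- gb[mapped]
  if (nrow(recs) == 0L) return(empty_spans(n_unmapped))
  lo <- pmin(ga, gb); hi <- pmax(ga, gb)
  key <- paste(lo, hi, sep = "\t")
  idx <- split(seq_along(key), key)
  keys <- names(idx)
  taxa <- lapply(idx, function(i) sort(unique(recs$taxid[i])))
  sources <- lapply(idx, function(i) sort(unique(recs$source[i])))
  parts <- strsplit(keys, "\t", fixed = TRUE)
  out <- data.frame(group_a = vapply(parts, `[[`, "", 1L),
                    group_b = vapply(parts, `[[`, "", 2L),
                    span = lengths(taxa), stringsAsFactors = FALSE)
  out$taxa <- unname(taxa)
  out$sources <- unname(sources)
  out <- out[order(out$group_a, out$group_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  class(out) <- c("ppi_spans", "data.frame")
  out
}

empty_spans <- function(n_unmapped) {
  out <- data.frame(group_a = character(), group_b = character(),
                    span = integer(), stringsAsFactors = FALSE)
  out$taxa <- list()
  out$sources <- list()
  attr(out, "n_unmapped") <- n_unmapped
  class(out) <- c("ppi_spans", "data.frame")
  out
}

#' Shared conserved PPIs per species pair
#'
#' For each unordered pair of taxa, the number of ortholog-group pairs whose
#' taxa set includes both (the quantity behind "species X and Y share N
#' PPIs").
#'
#' @param spans A `ppi_spans` object from [build_spans()].
#' @return data.frame with columns `taxid_a`, `taxid_b`, `n_shared`, sorted
#'   by count descending.
#' @export
species_pair_sharing <- function(spans) {
  stopifnot(inherits(spans, "ppi_spans"))
  multi <- spans$taxa[spans$span >= 2L]
  if (length(multi) == 0L) {
    return(data.frame(taxid_a = integer(), taxid_b = integer(),
                      n_shared = integer()))
  }
  pairs <- unlist(lapply(multi, function(tx) {
    cmb <- utils::combn(sort(tx), 2L)
    paste(cmb[1L, ], cmb[2L, ])
  }))
  tab <- table(pairs)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  out <- data.frame(taxid_a = as.integer(vapply(parts, `[[`, "", 1L)),
                    taxid_b = as.integer(vapply(parts, `[[`, "", 2L)),
                    n_shared = as.integer(tab))
  out <- out[order(-out$n_shared, out$taxid_a, out$taxid_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conserved-PPI counts per source database
#'
#' For each source database, the number of group pairs with span at or above
#' `min_span` that the database contains. Conservation requires observation
#' in at least two species, so `min_span < 2` is an error.
#'
#' @param spans A `ppi_spans` object.
#' @param min_span Minimum span defining "conserved" (>= 2).
#' @return Named integer vector database -> conserved-PPI count (all
#'   databases appearing in `spans` are present, including zeros).
#' @export
conserved_counts_by_database <- function(spans, min_span = 2L) {
  stopifnot(inherits(spans, "ppi_spans"))
  if (min_span < 2L) stop("min_span must be >= 2 (conservation requires at least two species)")
  all_dbs <- sort(unique(unlist(spans$sources)))
  counts <- stats::setNames(integer(length(all_dbs)), all_dbs)
  hits <- unlist(spans$sources[spans$span >= min_span])
  if (length(hits)) {
    tab <- table(hits)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Histogram of conservation spans
#'
#' Counts group pairs per span level, with an open top bin at `cap` (the
#' figure convention "found in `cap` or more species"). Bin counts sum to
#' the number of distinct group pairs.
#'
#' @param spans A `ppi_spans` object.
#' @param cap Top bin threshold (default 6: bins 1..5 and ">=6").
#' @return Named integer vector with names "1", ..., as.character(cap-1),
#'   ">=cap".
#' @export
span_histogram <- function(spans, cap = 6L) {
  stopifnot(inherits(spans, "ppi_spans"), cap >= 2L)
  lev <- span_levels(cap)
  counts <- stats::setNames(integer(length(lev)), lev)
  binned <- ifelse(spans$span >= cap, paste0(">=", cap),
                   as.character(spans$span))
  tab <- table(binned)
  counts[names(tab)] <- as.integer(tab)
  counts
}

span_levels <- function(cap) c(as.character(seq_len(cap - 1L)), paste0(">=", cap))

#' Write spans to TSV (taxa and sources semicolon-joined)
#' @param spans A `ppi_spans` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spans <- function(spans, path) {
  stopifnot(inherits(spans, "ppi_spans"))
  flat <- data.frame(
    group_a = spans$group_a, group_b = spans$group_b, span = spans$span,
    taxa = vapply(spans$taxa, paste, "", collapse = ";"),
    sources = vapply(spans$sources, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
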