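# identity substitution matrix over uppercase letters: match +1, mismatch 0
.identity_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters26 <- c(LETTERS, "*")
      mm <- matrix(0, length(letters26), length(letters26),
                   dimnames = list(letters26, letters26))
      diag(mm) <- 1
      m <<- mm
    }
    m
  }
})

#' Pairwise global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and linear
#' gap penalty -1 (via [Biostrings::pairwiseAlignment()]); identity is the
#' number of matched positions divided by the length of the *shorter*
#' sequence (the CD-HIT convention, robust to fragment entries).
#'
#' @param seq_a,seq_b Non-empty amino-acid strings.
#' @return Identity fraction in [0, 1].
#' @examples
#' pairwise_identity("AAAA", "AAAT")    # 0.75
#' pairwise_identity("AAAA", "AAAAAA")  # 1.0 (shorter-length normalization)
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (seq_a == seq_b) return(1)
  al <- Biostrings::pairwiseAlignment(seq_a, seq_b,
                                      substitutionMatrix = .identity_submat(),
                                      gapOpening = 0, gapExtension = 1,
                                      type = "global")
  Biostrings::nmatch(al) / min(nchar(seq_a), nchar(seq_b))
}

#' Greedy identity-threshold clustering of protein sequences
#'
#' Centroid-style greedy clustering: sequences are scanned in order of
#' decreasing length (ties broken by accession), each one joining the first
#' existing representative with [pairwise_identity()] at or above the
#' threshold, or founding a new cluster. Representatives are therefore
#' mutually below threshold in scan order, and the procedure is
#' deterministic.
#'
#' @param sequences Named character vector accession -> sequence.
#' @param threshold Identity threshold in (0, 1].
#' @return An object of class `cluster_assignment`: list with `threshold`
#'   and `rep_of` (named character vector member -> representative; every
#'   representative maps to itself).
#' @export
greedy_cluster <- function(sequences, threshold) {
  if (length(sequences) == 0L) stop("no sequences supplied")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("sequences must be named by accession")
  }
  stopifnot(threshold > 0, threshold <= 1)
  ord <- order(-nchar(sequences), names(sequences))
  acc <- names(sequences)[ord]
  seqs <- toupper(unname(sequences[ord]))
  reps <- character(0)
  rep_seq <- character(0)
  rep_of <- stats::setNames(character(length(acc)), acc)
  for (i in seq_along(acc)) {
    assigned <- NA_character_
    if (length(reps)) {
      # one vectorized global alignment of the query against every
      # representative, in creation order; identical scoring to
      # pairwise_identity()
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(rep_seq), seqs[i],
        substitutionMatrix = .identity_submat(),
        gapOpening = 0, gapExtension = 1, type = "global")
      ids <- Biostrings::nmatch(al) /
        pmin(nchar(rep_seq), nchar(seqs[i]))
      hit <- which(ids >= threshold)
      if (length(hit)) assigned <- reps[hit[1L]]
    }
    if (is.na(assigned)) {
      reps <- c(reps, acc[i])
      rep_seq <- c(rep_seq, seqs[i])
      assigned <- acc[i]
    }
    rep_of[acc[i]] <- assigned
  }
  structure(list(threshold = threshold, rep_of = rep_of),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Cluster assignment: %d members, %d clusters, identity threshold %.2f\n",
              length(x$rep_of), length(unique(x$rep_of)), x$threshold))
  invisible(x)
}

#' Write / read a cluster assignment as a two-column TSV
#'
#' Columns are (member, representative). The import path lets an external
#' clustering (e.g. MMseqs2 output reshaped to this form) replace the
#' internal greedy clusterer.
#'
#' @param assignment A `cluster_assignment`.
#' @param path TSV path.
#' @return For `write_clusters`, `path` invisibly; for `read_clusters`, a
#'   `cluster_assignment` (threshold recorded as `NA`).
#' @export
write_clusters <- function(assignment, path) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  utils::write.table(
    data.frame(member = names(assignment$rep_of),
               representative = unname(assignment$rep_of)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  map <- read_mapping(path)
  rep_of <- stats::setNames(as.character(map), names(map))
  reps <- unique(unname(rep_of))
  missing_self <- setdiff(reps, names(rep_of))
  if (length(missing_self)) {
    rep_of <- c(rep_of, stats::setNames(missing_self, missing_self))
  }
  structure(list(threshold = NA_real_, rep_of = rep_of),
            class = "cluster_assignment")
}

#' Remap a snapshot onto cluster representatives
#'
#' Replaces each accession by its cluster representative (accessions absent
#' from the assignment map to themselves), re-canonicalizes and
#' deduplicates. Pairs whose two members fall in the same cluster collapse
#' to a self-pair and are retained. Snapshot size never increases, and the
#' operation is idempotent.
#'
#' @param snapshot A [ppi_snapshot].
#' @param assignment A `cluster_assignment`.
#' @return The remapped [ppi_snapshot].
#' @export
remap_snapshot <- function(snapshot, assignment) {
  stopifnot(inherits(snapshot, "ppi_snapshot"),
            inherits(assignment, "cluster_assignment"))
  map <- assignment$rep_of
  fix <- function(x) {
    hit <- x %in% names(map)
    x[hit] <- unname(map[x[hit]])
    x
  }
  rec <- snapshot$records
  ppi_snapshot(snapshot$name, fix(rec$a), fix(rec$b), rec$taxid,
               stats = snapshot$stats)
}
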