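#' Read a PSI-MITAB 2.5/2.7 file into a snapshot
#'
#' Minimal MITAB ingestion: columns 1-2 carry the interactor identifiers
#' (the first `db:acc` token is used and the accession part kept), columns
#' 10-11 the interactor taxids (`taxid:NNNN`), column 12 the interaction
#' type (`psi-mi:"MI:NNNN"`). Records whose two taxids differ are dropped
#' and counted, because the downstream species grouping requires a single
#' species per interaction. When `allowed_interaction_types` is non-empty,
#' records whose interaction-type identifier is not in the list are dropped;
#' the default allow-list keeps physical association (MI:0915) and direct
#' interaction (MI:0407), mirroring the use of physical-only releases.
#'
#' @param path Path to a MITAB TSV (plain or gzip).
#' @param name Snapshot label; defaults to the file name.
#' @param allowed_interaction_types Character vector of MI identifiers;
#'   empty vector disables the filter.
#' @param default_taxid Taxid assigned to records lacking one; if `NULL`
#'   such records are dropped and counted.
#' @return A [ppi_snapshot] whose `stats` field reports per-stage counts
#'   (n_read, n_malformed, n_filtered, n_cross_species, n_no_taxid).
#' @export
read_mitab <- function(path, name = basename(path),
                       allowed_interaction_types = c("MI:0915", "MI:0407"),
                       default_taxid = NULL) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  is_comment <- startsWith(lines, "#")
  lines <- lines[!is_comment]
  n_read <- length(lines)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  malformed <- nf < 15L
  n_malformed <- sum(malformed)
  fields <- fields[!malformed]

  acc_a <- vapply(fields, function(f) mitab_accession(f[[1L]]), "")
  acc_b <- vapply(fields, function(f) mitab_accession(f[[2L]]), "")
  tax_a <- vapply(fields, function(f) mitab_taxid(f[[10L]]), NA_integer_)
  tax_b <- vapply(fields, function(f) mitab_taxid(f[[11L]]), NA_integer_)
  itype <- vapply(fields, function(f) mitab_mi_id(f[[12L]]), NA_character_)

  bad_acc <- !nzchar(acc_a) | !nzchar(acc_b)
  n_malformed <- n_malformed + sum(bad_acc)
  keep <- !bad_acc

  n_filtered <- 0L
  if (length(allowed_interaction_types) > 0L) {
    pass <- !is.na(itype) & itype %in% allowed_interaction_types
    n_filtered <- sum(keep & !pass)
    keep <- keep & pass
  }

  cross <- keep & !is.na(tax_a) & !is.na(tax_b) & tax_a != tax_b
  n_cross_species <- sum(cross)
  keep <- keep & !cross

  taxid <- ifelse(is.na(tax_a), tax_b, tax_a)
  no_tax <- keep & is.na(taxid)
  n_no_taxid <- 0L
  if (any(no_tax)) {
    if (is.null(default_taxid)) {
      n_no_taxid <- sum(no_tax)
      keep <- keep & !no_tax
    } else {
      taxid[no_tax] <- as.integer(default_taxid)
    }
  }

  snap <- ppi_snapshot(name, acc_a[keep], acc_b[keep], taxid[keep],
                       stats = list(n_read = n_read,
                                    n_malformed = n_malformed,
                                    n_filtered = n_filtered,
                                    n_cross_species = n_cross_species,
                                    n_no_taxid = n_no_taxid))
  if (nrow(snap$records) == 0L) {
    warning("snapshot '", name, "' has zero surviving records")
  }
  snap
}

# first db:acc token of a MITAB identifier field -> accession part
mitab_accession <- function(field) {
  tok <- strsplit(field, "|", fixed = TRUE)[[1L]][1L]
  if (is.na(tok) || tok == "-") return("")
  acc <- sub("^[^:]*:", "", tok)
  gsub('"', "", acc)
}

mitab_taxid <- function(field) {
  m <- regmatches(field, regexpr("taxid:(-?[0-9]+)", field))
  if (length(m) == 0L) return(NA_integer_)
  tid <- as.integer(sub("taxid:", "", m))
  if (!is.na(tid) && tid <= 0L) NA_integer_ else tid
}

mitab_mi_id <- function(field) {
  m <- regmatches(field, regexpr("MI:[0-9]{4}", field))
  if (length(m) == 0L) NA_character_ else m
}

# readLines through file(), which transparently decompresses gzip input
read_text_lines <- function(path) {
  con <- file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read a 2- or 3-column edge list into a snapshot
#'
#' Columns are `accA<TAB>accB[<TAB>taxid]`. With two columns a default
#' `taxid` must be supplied.
#'
#' @param path Path to the TSV (plain or gzip).
#' @param name Snapshot label; defaults to the file name.
#' @param taxid Default taxid for rows without a third column.
#' @return A [ppi_snapshot], canonicalized and deduplicated.
#' @export
read_edgelist <- function(path, name = basename(path), taxid = NULL) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    warning("snapshot '", name, "' has zero surviving records")
    return(ppi_snapshot(name))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) stop("edge list rows must have 2 or 3 columns")
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  tid <- ifelse(nf >= 3L, vapply(fields, function(f) f[min(3L, length(f))], ""), NA)
  tid <- suppressWarnings(as.integer(tid))
  if (anyNA(tid)) {
    if (is.null(taxid)) {
      stop("edge list has rows without a taxid column and no default taxid was given")
    }
    tid[is.na(tid)] <- as.integer(taxid)
  }
  ppi_snapshot(name, a, b, tid, stats = list(n_read = length(lines)))
}

#' Write a snapshot as a 3-column edge list
#'
#' Output round-trips through [read_edgelist()]: re-reading reproduces the
#' identical record-key set.
#'
#' @param snapshot A [ppi_snapshot].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(snapshot, path) {
  stopifnot(inherits(snapshot, "ppi_snapshot"))
  utils::write.table(snapshot$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 2-column mapping table (key, value) as a named character vector
#'
#' Used for secondary-to-primary accession maps, accession-to-ortholog-group
#' maps and accession-to-taxid maps. Keys must be unique; a key appearing
#' with several distinct values (e.g. a protein assigned to multiple
#' ortholog groups) is rejected and counted, since the analysis requires a
#' single group per protein at the chosen taxonomic level.
#'
#' @param path Path to the TSV (plain or gzip).
#' @return Named character vector; attribute `n_multimapped` counts the
#'   rejected multi-value keys.
#' @export
read_mapping <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(character())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) stop("mapping table rows must have 2 columns")
  k <- vapply(fields, `[[`, "", 1L)
  v <- vapply(fields, `[[`, "", 2L)
  dup <- duplicated(paste(k, v, sep = "\t"))
  k <- k[!dup]; v <- v[!dup]
  multi <- k %in% k[duplicated(k)]
  out <- stats::setNames(v[!multi], k[!multi])
  attr(out, "n_multimapped") <- length(unique(k[multi]))
  out
}

#' Write a mapping table
#' @param map Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(map, path) {
  utils::write.table(data.frame(names(map), as.character(map)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Normalize snapshot accessions to primary IDs
#'
#' Inconsistent identifier use between databases (secondary accessions,
#' isoform suffixes) inflates apparent disagreement. Each accession is
#' first stripped of an isoform suffix (a trailing dash plus digits) when
#' `strip_isoform` is `TRUE` -- applied only to UniProt-shaped accessions so
#' that other identifier schemes are not corrupted -- then replaced by its
#' primary ID when present in the map. Unmapped accessions pass through
#' unchanged. The result is re-canonicalized and deduplicated, so the
#' snapshot never grows; the operation is idempotent.
#'
#' @param snapshot A [ppi_snapshot].
#' @param secondary_to_primary Named character vector mapping secondary to
#'   primary accessions (may be empty).
#' @param strip_isoform Strip `-N` isoform suffixes from UniProt-shaped IDs.
#' @return A normalized [ppi_snapshot].
#' @export
normalize_accessions <- function(snapshot, secondary_to_primary = character(),
                                 strip_isoform = TRUE) {
  stopifnot(inherits(snapshot, "ppi_snapshot"))
  fix <- function(x) {
    if (strip_isoform) {
      iso <- grepl(uniprot_isoform_regex(), x)
      x[iso] <- sub("-[0-9]+$", "", x[iso])
    }
    hit <- x %in% names(secondary_to_primary)
    x[hit] <- unname(secondary_to_primary[x[hit]])
    x
  }
  rec <- snapshot$records
  ppi_snapshot(snapshot$name, fix(rec$a), fix(rec$b), rec$taxid,
               stats = snapshot$stats)
}

# UniProt accession shape (6 or 10 characters) followed by an isoform suffix
uniprot_isoform_regex <- function() {
  "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})-[0-9]+$"
}

#' Read a FASTA file as a named character vector of sequences
#'
#' Sequences are uppercased. With `split_pipes = TRUE` (default), headers of
#' the UniProt style `>sp|ACC|NAME desc` yield the second pipe field as the
#' accession; plain headers yield the first whitespace token. Duplicate
#' accessions keep the last entry, with a warning.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @param split_pipes Interpret pipe-delimited headers (UniProt convention).
#' @return Named character vector accession -> sequence.
#' @export
read_fasta <- function(path, split_pipes = TRUE) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) return(character())
  hdr <- names(set)
  acc <- vapply(strsplit(hdr, "[ \t]"), `[[`, "", 1L)
  if (split_pipes) {
    piped <- grepl("|", acc, fixed = TRUE)
    acc[piped] <- vapply(strsplit(acc[piped], "|", fixed = TRUE),
                         function(f) f[min(2L, length(f))], "")
  }
  seqs <- toupper(as.character(set))
  if (anyDuplicated(acc)) {
    warning("duplicate FASTA accessions; last entry wins: ",
            paste(unique(acc[duplicated(acc)]), collapse = ", "))
    keep <- !duplicated(acc, fromLast = TRUE)
    acc <- acc[keep]; seqs <- seqs[keep]
  }
  stats::setNames(unname(seqs), acc)
}

#' Write sequences to FASTA
#' @param sequences Named character vector accession -> sequence.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  lines <- as.vector(rbind(paste0(">", names(sequences)),
                           unname(sequences)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a (multi-model) PDB file as a C-alpha ensemble
#'
#' Extracts C-alpha atoms per chain in residue order from each MODEL block
#' (a file without MODEL records is a one-model ensemble). All models must
#' share an identical (chain, residue-number) sequence; alternate locations
#' other than blank or "A" are skipped.
#'
#' @param path Path to a PDB-format file (plain or gzip).
#' @return A `ppi_ensemble`: list with `chain` (character per residue),
#'   `resno` (integer per residue), `chains` (chain order) and `coords`
#'   (array M x N x 3, Angstrom).
#' @export
read_pdb_ensemble <- function(path) {
  lines <- read_text_lines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) {
    blocks <- list(lines)
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts)) {
      stop("unbalanced MODEL/ENDMDL records")
    }
    blocks <- Map(function(s, e) lines[seq(s, e)], model_starts, model_ends)
  }
  models <- lapply(blocks, parse_ca_block)
  ref <- models[[1L]]
  if (nrow(ref) == 0L) stop("no C-alpha atoms found")
  ref_key <- paste(ref$chain, ref$resno)
  if (length(models) > 1L) {
    for (m in seq_along(models)[-1L]) {
      key <- paste(models[[m]]$chain, models[[m]]$resno)
      if (length(key) != length(ref_key) || any(key != ref_key)) {
        miss <- c(setdiff(ref_key, key), setdiff(key, ref_key),
                  "residue order differs")[1L]
        stop(sprintf("model %d residue set mismatch (first mismatch: %s)",
                     m, miss))
      }
    }
  }
  coords <- array(NA_real_, dim = c(length(models), nrow(ref), 3L))
  for (m in seq_along(models)) {
    coords[m, , ] <- as.matrix(models[[m]][, c("x", "y", "z")])
  }
  new_ensemble(ref$chain, ref$resno, coords)
}

parse_ca_block <- function(lines) {
  atom <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (length(atom) == 0L) {
    return(data.frame(chain = character(), resno = integer(),
                      x = double(), y = double(), z = double()))
  }
  aname <- trimws(substr(atom, 13L, 16L))
  altloc <- substr(atom, 17L, 17L)
  sel <- aname == "CA" & altloc %in% c(" ", "", "A")
  atom <- atom[sel]
  data.frame(
    chain = substr(atom, 22L, 22L),
    resno = as.integer(substr(atom, 23L, 26L)),
    x = as.numeric(substr(atom, 31L, 38L)),
    y = as.numeric(substr(atom, 39L, 46L)),
    z = as.numeric(substr(atom, 47L, 54L)),
    stringsAsFactors = FALSE
  )
}

#' Construct a C-alpha ensemble
#'
#' @param chain Character vector of chain IDs per residue.
#' @param resno Integer residue numbers per residue.
#' @param coords Numeric array M x N x 3 (models x residues x xyz), or an
#'   N x 3 matrix for a single conformation.
#' @return A `ppi_ensemble` object.
#' @export
new_ensemble <- function(chain, resno, coords) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3L] == 3L,
            dim(coords)[2L] == length(chain), length(chain) == length(resno))
  if (any(!is.finite(coords))) stop("ensemble coordinates must be finite")
  structure(list(chain = as.character(chain), resno = as.integer(resno),
                 chains = unique(as.character(chain)), coords = coords),
            class = "ppi_ensemble")
}

#' @export
print.ppi_ensemble <- function(x, ...) {
  cat(sprintf("C-alpha ensemble: %d models, %d residues, chains %s\n",
              dim(x$coords)[1L], dim(x$coords)[2L],
              paste(x$chains, collapse = ",")))
  invisible(x)
}

#' Number of models in an ensemble
#' @param ensemble A `ppi_ensemble`.
#' @return Integer model count.
#' @export
n_models <- function(ensemble) dim(ensemble$coords)[1L]

#' Coordinates of one conformation
#' @param ensemble A `ppi_ensemble`.
#' @param model Model index.
#' @return N x 3 numeric matrix.
#' @export
ensemble_coords <- function(ensemble, model = 1L) {
  ensemble$coords[model, , , drop = TRUE]
}

#' Write an ensemble as a multi-model PDB file
#'
#' C-alpha-only ATOM records wrapped in MODEL/ENDMDL blocks; round-trips
#' through [read_pdb_ensemble()] to coordinate precision (0.001 Angstrom).
#'
#' @param ensemble A `ppi_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  nm <- n_models(ensemble)
  n <- dim(ensemble$coords)[2L]
  for (m in seq_len(nm)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- ensemble$coords[m, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n), ensemble$chain, ensemble$resno,
      xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
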