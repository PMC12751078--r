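#' Construct a structure index
#'
#' Records which ortholog-group pairs have at least one deposited complex
#' structure. A group pair is "solved" if any member pair has any PDB
#' complex ID in the index; structure contents are not validated.
#'
#' @param group_a,group_b Group IDs of indexed pairs (canonicalized).
#' @param pdb_id 4-character alphanumeric PDB identifiers.
#' @return An object of class `structure_index`: list with `solved`
#'   (character keys "group_a\\tgroup_b") and `evidence` (named list of
#'   sorted PDB ID vectors).
#' @export
structure_index <- function(group_a = character(), group_b = character(),
                            pdb_id = character()) {
  stopifnot(length(group_a) == length(group_b),
            length(group_a) == length(pdb_id))
  if (length(pdb_id) && any(!grepl("^[0-9A-Za-z]{4}$", pdb_id))) {
    stop("PDB IDs must be 4-character alphanumeric")
  }
  lo <- pmin(group_a, group_b); hi <- pmax(group_a, group_b)
  key <- paste(lo, hi, sep = "\t")
  evidence <- lapply(split(toupper(pdb_id), key), function(x) sort(unique(x)))
  structure(list(solved = sort(unique(key)), evidence = evidence),
            class = "structure_index")
}

#' Read a structure index from TSV (group_a, group_b, pdb_id)
#' @param path Path to the TSV (plain or gzip).
#' @return A `structure_index`.
#' @export
read_structure_index <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(structure_index())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 3L)) stop("structure index rows must have 3 columns")
  structure_index(vapply(f, `[[`, "", 1L), vapply(f, `[[`, "", 2L),
                  vapply(f, `[[`, "", 3L))
}

#' Write a structure index to TSV
#' @param index A `structure_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_index <- function(index, path) {
  stopifnot(inherits(index, "structure_index"))
  rows <- lapply(names(index$evidence), function(k) {
    g <- strsplit(k, "\t", fixed = TRUE)[[1L]]
    data.frame(group_a = g[1L], group_b = g[2L],
               pdb_id = index$evidence[[k]], stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group_a = character(), group_b = character(),
               pdb_id = character())
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

span_key <- function(spans) paste(spans$group_a, spans$group_b, sep = "\t")

#' Structure coverage by conservation span
#'
#' Stratifies group pairs by span level (1 .. cap-1 and ">=cap") and counts
#' pairs with and without a deposited complex structure. The proportion is
#' `NaN` for empty levels.
#'
#' @param spans A `ppi_spans` object.
#' @param index A `structure_index`.
#' @param cap Top bin threshold (default 6).
#' @return data.frame with columns `level`, `n_solved`, `n_unsolved`,
#'   `proportion`.
#' @export
coverage_by_span <- function(spans, index, cap = 6L) {
  stopifnot(inherits(spans, "ppi_spans"), inherits(index, "structure_index"),
            cap >= 2L)
  solved <- span_key(spans) %in% index$solved
  lev <- ifelse(spans$span >= cap, paste0(">=", cap), as.character(spans$span))
  levels_all <- span_levels(cap)
  n_solved <- n_unsolved <- integer(length(levels_all))
  for (i in seq_along(levels_all)) {
    sel <- lev == levels_all[i]
    n_solved[i] <- sum(sel & solved)
    n_unsolved[i] <- sum(sel & !solved)
  }
  data.frame(level = levels_all, n_solved = n_solved,
             n_unsolved = n_unsolved,
             proportion = n_solved / (n_solved + n_unsolved),
             stringsAsFactors = FALSE)
}

#' Odds ratio of structure coverage vs the non-conserved baseline
#'
#' For a 2x2 table with `a` solved / `b` unsolved pairs at a span level and
#' `c` solved / `d` unsolved at baseline (span 1, "non-conserved"), the odds
#' ratio is (a/b)/(c/d). When any cell is zero and the correction is
#' enabled, 0.5 is added to all four cells (Haldane-Anscombe) -- the highly
#' conserved levels are small and nearly fully solved, so zero unsolved
#' cells do occur. The 95% CI uses the log-OR normal approximation
#' exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)). Fisher's exact p-value
#' is reported alongside.
#'
#' @param row_s List or one-row data.frame with `n_solved`, `n_unsolved` at
#'   the span level of interest.
#' @param row_baseline Same for the baseline (span-1) level.
#' @param zero_cell_correction Apply the Haldane-Anscombe 0.5 correction to
#'   zero cells (default `TRUE`).
#' @return List with `odds_ratio`, `ci_low`, `ci_high`, `fisher_p`
#'   (all `NA` when the baseline level is empty).
#' @export
odds_ratio_vs_baseline <- function(row_s, row_baseline,
                                   zero_cell_correction = TRUE) {
  a <- as.numeric(row_s$n_solved);       b <- as.numeric(row_s$n_unsolved)
  cc <- as.numeric(row_baseline$n_solved); d <- as.numeric(row_baseline$n_unsolved)
  if (cc + d == 0 || a + b == 0) {
    return(list(odds_ratio = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, fisher_p = NA_real_))
  }
  fisher_p <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2L,
                                        byrow = TRUE))$p.value
  if (zero_cell_correction && any(c(a, b, cc, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  if (any(c(b, cc) == 0)) {
    return(list(odds_ratio = Inf, ci_low = NA_real_, ci_high = NA_real_,
                fisher_p = fisher_p))
  }
  or <- (a / b) / (cc / d)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  list(odds_ratio = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se),
       fisher_p = fisher_p)
}

#' Full structure-coverage enrichment table
#'
#' [coverage_by_span()] augmented with the odds ratio of each span level
#' against the span-1 (non-conserved) baseline.
#'
#' @inheritParams coverage_by_span
#' @param zero_cell_correction Passed to [odds_ratio_vs_baseline()].
#' @return data.frame with columns level, n_solved, n_unsolved, proportion,
#'   odds_ratio, ci_low, ci_high, fisher_p. The baseline row has
#'   odds_ratio 1 by definition.
#' @export
enrichment_table <- function(spans, index, cap = 6L,
                             zero_cell_correction = TRUE) {
  cov <- coverage_by_span(spans, index, cap)
  base <- cov[cov$level == "1", , drop = FALSE]
  ors <- lapply(seq_len(nrow(cov)), function(i) {
    if (cov$level[i] == "1") {
      list(odds_ratio = 1, ci_low = NA_real_, ci_high = NA_real_,
           fisher_p = NA_real_)
    } else {
      odds_ratio_vs_baseline(cov[i, ], base, zero_cell_correction)
    }
  })
  cov$odds_ratio <- vapply(ors, `[[`, 0, "odds_ratio")
  cov$ci_low <- vapply(ors, `[[`, 0, "ci_low")
  cov$ci_high <- vapply(ors, `[[`, 0, "ci_high")
  cov$fisher_p <- vapply(ors, `[[`, 0, "fisher_p")
  cov
}

#' Conserved group pairs with no deposited structure
#'
#' The "remaining to be solved" listing: group pairs with span at or above
#' `min_span` and no PDB evidence, sorted by span descending then
#' lexicographically.
#'
#' @param spans A `ppi_spans` object.
#' @param index A `structure_index`.
#' @param min_span Minimum span (>= 2).
#' @return data.frame with columns `group_a`, `group_b`, `span`, `taxa`
#'   (semicolon-joined).
#' @export
unsolved_pairs <- function(spans, index, min_span = 2L) {
  stopifnot(inherits(spans, "ppi_spans"), inherits(index, "structure_index"))
  if (min_span < 2L) stop("min_span must be >= 2")
  sel <- spans$span >= min_span & !(span_key(spans) %in% index$solved)
  out <- data.frame(group_a = spans$group_a[sel],
                    group_b = spans$group_b[sel],
                    span = spans$span[sel],
                    taxa = vapply(spans$taxa[sel], paste, "", collapse = ";"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$span, out$group_a, out$group_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
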