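#' Kabsch least-squares rigid superposition
#'
#' Closed-form optimal rotation and translation minimizing the (optionally
#' weighted) RMSD between paired point sets, via singular value
#' decomposition with proper-rotation enforcement (sign flip of the smallest
#' singular vector when the determinant is negative).
#'
#' @param ref_coords,mov_coords N x 3 matrices of paired points (N >= 3,
#'   not all collinear).
#' @param weights Optional non-negative per-point weights.
#' @return An object of class `superposition`: list with `rotation` (3x3,
#'   det +1), `translation` (length-3), and `rmsd` (Angstrom), such that
#'   `mov %*% t(rotation) + translation` best fits `ref`.
#' @export
kabsch_superpose <- function(ref_coords, mov_coords, weights = NULL) {
  ref <- as.matrix(ref_coords); mov <- as.matrix(mov_coords)
  if (!all(dim(ref) == dim(mov)) || ncol(ref) != 3L) {
    stop("ref and mov must be N x 3 matrices of equal size")
  }
  n <- nrow(ref)
  if (n < 3L) stop("at least 3 points required")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative with positive sum")
  }
  w <- weights / sum(weights)
  cref <- colSums(ref * w)
  cmov <- colSums(mov * w)
  rc <- sweep(ref, 2L, cref)
  mc <- sweep(mov, 2L, cmov)
  sv_ref <- svd(rc * sqrt(w))$d
  if (sv_ref[2L] < 1e-9 * max(sv_ref[1L], 1e-12)) {
    stop("degenerate (collinear) point set: superposition rotation is not unique")
  }
  h <- t(mc * w) %*% rc              # 3x3 cross-covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- mc %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - rc)^2)))
  structure(list(rotation = rot,
                 translation = as.vector(cref - rot %*% cmov),
                 rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param coords N x 3 matrix.
#' @param sp A `superposition` from [kabsch_superpose()].
#' @return Transformed N x 3 matrix.
#' @export
apply_superposition <- function(coords, sp) {
  sweep(as.matrix(coords) %*% t(sp$rotation), 2L, sp$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Rigid superposition: RMSD %.4f A\n", x$rmsd))
  invisible(x)
}

#' Per-residue root-mean-square fluctuation
#'
#' Each conformation is superposed onto an iteratively refined mean
#' structure (two refinement passes: fit to the first model, average, refit
#' to the average, average again), using the residues in `fit_selection` for
#' the fit; the RMSF of residue i is then
#' sqrt(mean_m |x_mi - xbar_i|^2) over the fitted conformations. Invariant
#' under a global rigid motion of every conformation.
#'
#' @param ensemble A `ppi_ensemble` with at least 2 models.
#' @param fit_selection Integer residue indices used for the superposition
#'   fit (default: all residues).
#' @return data.frame with columns `chain`, `resno`, `rmsf` (Angstrom).
#' @export
rmsf <- function(ensemble, fit_selection = NULL) {
  stopifnot(inherits(ensemble, "ppi_ensemble"))
  m <- n_models(ensemble)
  if (m < 2L) stop("RMSF requires at least 2 models")
  n <- dim(ensemble$coords)[2L]
  sel <- if (is.null(fit_selection)) seq_len(n) else as.integer(fit_selection)
  stopifnot(all(sel >= 1L), all(sel <= n), length(sel) >= 3L)
  fitted <- ensemble$coords
  ref <- fitted[1L, , , drop = TRUE]
  for (pass in 1:2) {
    for (i in seq_len(m)) {
      xyz <- fitted[i, , , drop = TRUE]
      sp <- kabsch_superpose(ref[sel, , drop = FALSE],
                             xyz[sel, , drop = FALSE])
      fitted[i, , ] <- apply_superposition(xyz, sp)
    }
    ref <- apply(fitted, c(2L, 3L), mean)
  }
  dev2 <- vapply(seq_len(m), function(i) {
    rowSums((fitted[i, , , drop = TRUE] - ref)^2)
  }, numeric(n))
  data.frame(chain = ensemble$chain, resno = ensemble$resno,
             rmsf = sqrt(rowMeans(matrix(dev2, nrow = n))),
             stringsAsFactors = FALSE)
}

#' Inter-chain contact frequency across an ensemble
#'
#' For every residue pair (i in chain_a, j in chain_b), the fraction of
#' models in which the C-alpha--C-alpha distance is at or below `cutoff`.
#'
#' @param ensemble A `ppi_ensemble`.
#' @param chain_a,chain_b Chain identifiers (must be present).
#' @param cutoff Contact distance cutoff in Angstrom (default 8).
#' @return An object of class `contact_map`: list with `freq` (matrix of
#'   fractions, rows = chain_a residues, cols = chain_b residues, dimnames
#'   are residue numbers), `rows`, `cols`, `cutoff`.
#' @export
contact_frequency <- function(ensemble, chain_a, chain_b, cutoff = 8) {
  stopifnot(inherits(ensemble, "ppi_ensemble"), cutoff > 0)
  ia <- which(ensemble$chain == chain_a)
  ib <- which(ensemble$chain == chain_b)
  if (length(ia) == 0L) stop("chain '", chain_a, "' not present in ensemble")
  if (length(ib) == 0L) stop("chain '", chain_b, "' not present in ensemble")
  m <- n_models(ensemble)
  freq <- matrix(0, length(ia), length(ib),
                 dimnames = list(ensemble$resno[ia], ensemble$resno[ib]))
  cut2 <- cutoff^2
  for (k in seq_len(m)) {
    xyz <- ensemble$coords[k, , , drop = TRUE]
    a <- xyz[ia, , drop = FALSE]
    b <- xyz[ib, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    freq <- freq + (d2 <= cut2)
  }
  structure(list(freq = freq / m, rows = ensemble$resno[ia],
                 cols = ensemble$resno[ib], cutoff = cutoff,
                 chain_a = chain_a, chain_b = chain_b),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("Contact map %s x %s (%d x %d residues, cutoff %.1f A), max frequency %.2f\n",
              x$chain_a, x$chain_b, nrow(x$freq), ncol(x$freq), x$cutoff,
              if (length(x$freq)) max(x$freq) else NA))
  invisible(x)
}

#' Write a contact map as a matrix TSV with residue labels
#' @param map A `contact_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  utils::write.table(map$freq, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' TM-score length-normalization distance d0
#' @param l_target Reference (target) length; must be >= 16 so d0 > 0.
#' @return d0 in Angstrom: 1.24 (L-15)^(1/3) - 1.8.
#' @export
tm_d0 <- function(l_target) {
  if (l_target < 16L) stop("TM-score requires reference length >= 16")
  1.24 * (l_target - 15)^(1 / 3) - 1.8
}

#' Template-modelling score of a model against a reference
#'
#' TM = max over superpositions of (1/L_t) sum_i 1 / (1 + (d_i/d0)^2) with
#' d0 = 1.24 (L_t - 15)^(1/3) - 1.8 and L_t the reference length. The
#' residue correspondence is supplied, not searched (structural alignment is
#' out of scope). Maximization follows the standard iterative scheme:
#' initial fits on the full correspondence and on sliding fragments of
#' length L, L/2 and L/4; for each seed the superposition is refined by
#' refitting on the residues within a distance threshold that starts at
#' d0 + 1 Angstrom and shrinks by 0.5 to a floor of 1.5, each inner loop
#' converging when the retained-residue set repeats; the best score over all
#' seeds is kept. Scores are in (0, 1]; > 0.5 conventionally indicates the
#' same fold. Invariant under rigid motions of the model.
#'
#' @param model,reference `ppi_ensemble` objects (first model used) or
#'   N x 3 coordinate matrices.
#' @param correspondence Two-column integer matrix of (model row, reference
#'   row) index pairs; `NULL` means row i matches row i.
#' @param l_target Normalization length (default: number of reference
#'   residues; must be >= 16).
#' @return List with `tm`, `d0` and the best `superposition`.
#' @export
tm_score <- function(model, reference, correspondence = NULL,
                     l_target = NULL) {
  mc <- if (inherits(model, "ppi_ensemble")) ensemble_coords(model) else as.matrix(model)
  rc <- if (inherits(reference, "ppi_ensemble")) ensemble_coords(reference) else as.matrix(reference)
  if (is.null(correspondence)) {
    if (nrow(mc) != nrow(rc)) {
      stop("coordinates differ in length; supply an explicit correspondence")
    }
    correspondence <- cbind(seq_len(nrow(mc)), seq_len(nrow(rc)))
  }
  correspondence <- as.matrix(correspondence)
  if (nrow(correspondence) == 0L) stop("correspondence is empty")
  if (is.null(l_target)) l_target <- nrow(rc)
  d0 <- tm_d0(l_target)
  mm <- mc[correspondence[, 1L], , drop = FALSE]
  rr <- rc[correspondence[, 2L], , drop = FALSE]
  l <- nrow(mm)

  score_of <- function(sp) {
    d <- sqrt(rowSums((apply_superposition(mm, sp) - rr)^2))
    list(tm = sum(1 / (1 + (d / d0)^2)) / l_target, d = d)
  }

  best <- list(tm = -Inf, sp = NULL)
  try_seed <- function(sel) {
    if (length(sel) < 3L) return()
    sp <- tryCatch(kabsch_superpose(rr[sel, , drop = FALSE],
                                    mm[sel, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(sp)) return()
    sc <- score_of(sp)
    if (sc$tm > best$tm) best <<- list(tm = sc$tm, sp = sp)
    cuts <- d0 + 1
    if (cuts > 1.5) cuts <- seq(d0 + 1, 1.5, by = -0.5)
    cuts <- pmax(cuts, 1.5)
    for (cut in cuts) {
      cur <- sel
      seen <- character(0)
      repeat {
        key <- paste(cur, collapse = ",")
        if (key %in% seen) break
        seen <- c(seen, key)
        sp <- tryCatch(kabsch_superpose(rr[cur, , drop = FALSE],
                                        mm[cur, , drop = FALSE]),
                       error = function(e) NULL)
        if (is.null(sp)) break
        sc <- score_of(sp)
        if (sc$tm > best$tm) best <<- list(tm = sc$tm, sp = sp)
        nxt <- which(sc$d < cut)
        if (length(nxt) < 3L) break
        cur <- nxt
      }
    }
  }

  for (fl in unique(pmax(c(l, l %/% 2L, l %/% 4L), 4L))) {
    if (fl > l) next
    step <- max(1L, fl %/% 2L)
    for (start in seq(1L, l - fl + 1L, by = step)) {
      try_seed(seq(start, start + fl - 1L))
    }
  }
  if (!is.finite(best$tm)) stop("no valid superposition seed (degenerate coordinates)")
  list(tm = min(best$tm, 1), d0 = d0, superposition = best$sp)
}

#' Fraction of ensemble models in the reference fold
#'
#' Scores every conformation of each ensemble against a reference structure
#' with [tm_score()] and reports the fraction above the fold threshold
#' (conventionally 0.5).
#'
#' @param ensembles A `ppi_ensemble` or list of them.
#' @param reference `ppi_ensemble` (first model used) or N x 3 matrix.
#' @param correspondence Passed to [tm_score()].
#' @param threshold TM-score fold threshold (default 0.5).
#' @param l_target Passed to [tm_score()].
#' @return data.frame with one row per ensemble: `n_models`,
#'   `fraction_above`, `mean_tm`.
#' @export
fold_consistency <- function(ensembles, reference, correspondence = NULL,
                             threshold = 0.5, l_target = NULL) {
  if (inherits(ensembles, "ppi_ensemble")) ensembles <- list(ensembles)
  rows <- lapply(seq_along(ensembles), function(i) {
    e <- ensembles[[i]]
    tms <- vapply(seq_len(n_models(e)), function(m) {
      tm_score(ensemble_coords(e, m), reference, correspondence,
               l_target)$tm
    }, 0)
    data.frame(ensemble = i, n_models = length(tms),
               fraction_above = mean(tms > threshold), mean_tm = mean(tms))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
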