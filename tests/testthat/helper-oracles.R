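# Brute-force oracles, kept deliberately independent of the implementation
# paths they check: per-key enumeration for set operations, dictionary
# accumulation for spans/coverage, BFS for components, random-rotation
# search for superposition.

# exclusive intersections: test every union key against every set
oracle_exclusive <- function(sets) {
  ord <- order(-lengths(sets), names(sets))
  sets <- sets[ord]
  counts <- list()
  for (key in unique(unlist(sets, use.names = FALSE))) {
    present <- names(sets)[vapply(sets, function(s) key %in% s, TRUE)]
    sig <- paste(present, collapse = "&")
    counts[[sig]] <- (counts[[sig]] %||% 0L) + 1L
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_shared_at_least <- function(sets, k) {
  keys <- unique(unlist(sets, use.names = FALSE))
  hits <- vapply(keys, function(key) {
    sum(vapply(sets, function(s) key %in% s, TRUE))
  }, 0L)
  sort(keys[hits >= k])
}

# spans: dictionary accumulation over individual records
oracle_spans <- function(records, acc2group) {
  taxa <- list(); sources <- list()
  for (i in seq_len(nrow(records))) {
    ga <- acc2group[records$a[i]]; gb <- acc2group[records$b[i]]
    if (is.na(ga) || is.na(gb)) next
    key <- paste(min(ga, gb), max(ga, gb), sep = "\t")
    taxa[[key]] <- union(taxa[[key]] %||% integer(), records$taxid[i])
    sources[[key]] <- union(sources[[key]] %||% character(),
                            records$source[i])
  }
  keys <- sort(names(taxa))
  list(keys = keys,
       taxa = lapply(taxa[keys], function(x) sort(x)),
       sources = lapply(sources[keys], function(x) sort(x)))
}

oracle_coverage <- function(span_df, solved_keys, cap) {
  levels_all <- c(as.character(seq_len(cap - 1L)), paste0(">=", cap))
  n_s <- n_u <- stats::setNames(integer(length(levels_all)), levels_all)
  for (i in seq_len(nrow(span_df))) {
    lev <- if (span_df$span[i] >= cap) paste0(">=", cap) else
      as.character(span_df$span[i])
    key <- paste(span_df$group_a[i], span_df$group_b[i], sep = "\t")
    if (key %in% solved_keys) n_s[lev] <- n_s[lev] + 1L else
      n_u[lev] <- n_u[lev] + 1L
  }
  list(n_solved = unname(n_s), n_unsolved = unname(n_u))
}

# connected components by BFS over an edge list (self-loops never connect)
oracle_components <- function(nodes, edge_a, edge_b) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(edge_a)) {
    if (edge_a[i] != edge_b[i]) {
      adj[[edge_a[i]]] <- c(adj[[edge_a[i]]], edge_b[i])
      adj[[edge_b[i]]] <- c(adj[[edge_b[i]]], edge_a[i])
    }
  }
  seen <- character(0)
  comps <- list()
  for (start in nodes) {
    if (start %in% seen) next
    queue <- start
    comp <- character(0)
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  n_edges <- vapply(comps, function(cmp) {
    sum(edge_a %in% cmp & edge_b %in% cmp)
  }, 0L)
  ord <- order(-lengths(comps), -n_edges,
               vapply(comps, min, ""))
  comps[ord]
}

# random snapshot family over a small key pool
random_key_family <- function(n_dbs, pool_size, seed) {
  set.seed(seed)
  pool <- sprintf("K%04d\tK%04d\t%d",
                  sample.int(500, pool_size, replace = TRUE),
                  500 + sample.int(500, pool_size, replace = TRUE),
                  sample.int(3, pool_size, replace = TRUE) + 9605L)
  pool <- unique(pool)
  sets <- lapply(seq_len(n_dbs), function(i) {
    sample(pool, sample.int(length(pool), 1L))
  })
  names(sets) <- paste0("set", letters[seq_len(n_dbs)])
  sets
}

# uniform random proper rotation (QR of a Gaussian matrix, det corrected)
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# best rmsd over n random rotations (translation optimal per rotation)
oracle_min_rmsd <- function(ref, mov, n_rot = 1000L) {
  rc <- sweep(ref, 2L, colMeans(ref))
  mc <- sweep(mov, 2L, colMeans(mov))
  best <- Inf
  for (i in seq_len(n_rot)) {
    r <- random_rotation()
    d <- sqrt(mean(rowSums((mc %*% t(r) - rc)^2)))
    if (d < best) best <- d
  }
  best
}

# numerical search over rotations (axis-angle parameterization, Rodrigues
# formula) with centroid-aligned translation; independent of the SVD path
oracle_opt_rmsd <- function(ref, mov, n_starts = 8L) {
  rc <- sweep(ref, 2L, colMeans(ref))
  mc <- sweep(mov, 2L, colMeans(mov))
  rodrigues <- function(p) {
    theta <- sqrt(sum(p^2))
    if (theta < 1e-12) return(diag(3))
    k <- p / theta
    kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
                 3, 3, byrow = TRUE)
    diag(3) + sin(theta) * kx + (1 - cos(theta)) * kx %*% kx
  }
  obj <- function(p) sqrt(mean(rowSums((mc %*% t(rodrigues(p)) - rc)^2)))
  best <- Inf
  starts <- rbind(c(0, 0, 0),
                  matrix(stats::rnorm(3L * (n_starts - 1L)), ncol = 3L))
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (fit$value < best) best <- fit$value
  }
  best
}

# symmetric point cloud on a sphere whose radial expansion by d0 leaves the
# identity superposition optimal with every residue at distance exactly d0
d0_displacement_fixture <- function(n_pairs = 16L, radius = 10, seed = 7L) {
  set.seed(seed)
  u <- matrix(stats::rnorm(3L * n_pairs), n_pairs, 3L)
  u <- u / sqrt(rowSums(u^2))
  pts <- radius * u
  # interleave each point with its antipode so contiguous fragments stay
  # centrosymmetric
  ref <- matrix(0, 2L * n_pairs, 3L)
  ref[seq(1L, 2L * n_pairs, 2L), ] <- pts
  ref[seq(2L, 2L * n_pairs, 2L), ] <- -pts
  d0 <- ppiconserve::tm_d0(nrow(ref))
  model <- ref * (radius + d0) / radius
  list(ref = ref, model = model, d0 = d0)
}
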