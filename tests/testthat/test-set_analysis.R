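test_that("canonical_pair is order-invariant, idempotent and rejects empties", {
  expect_equal(canonical_pair("Q2", "Q1"), c("Q1", "Q2"))
  expect_equal(canonical_pair("P1", "P1"), c("P1", "P1"))
  expect_error(canonical_pair("", "B"), "non-empty")
  set.seed(42)
  for (i in 1:100) {
    a <- paste(sample(LETTERS, 4), collapse = "")
    b <- paste(sample(LETTERS, 4), collapse = "")
    expect_identical(canonical_pair(a, b), canonical_pair(b, a))
    cp <- canonical_pair(a, b)
    expect_identical(canonical_pair(cp[1], cp[2]), cp)
  }
})

test_that("pair combinatorics follows choose(n, 2) exactly", {
  expect_equal(n_possible_pairs(2), 1)
  expect_equal(n_possible_pairs(0), 0)
  expect_equal(n_possible_pairs(4000), choose(4000, 2))
  expect_equal(n_possible_pairs(20000), choose(20000, 2))
  expect_error(n_possible_pairs(-1), "non-negative")
})

test_that("exclusive intersections partition the union", {
  A <- ppi_snapshot("A", c("x1", "y1"), c("x2", "y2"), 9606L)
  B <- ppi_snapshot("B", c("y1", "z1"), c("y2", "z2"), 9606L)
  sig <- exclusive_intersections(list(A, B))
  got <- setNames(sig$count, sig$signature)
  expect_equal(got[["A"]], 1L)
  expect_equal(got[["B"]], 1L)
  expect_equal(got[["A&B"]], 1L)
  expect_equal(sum(sig$count), 3L)

  # disjoint snapshots give only singleton signatures
  C <- ppi_snapshot("C", "q1", "q2", 9606L)
  sig2 <- exclusive_intersections(list(A, C))
  expect_true(all(sig2$degree == 1L))

  # identical snapshots give one full signature
  A2 <- ppi_snapshot("A2", c("x1", "y1"), c("x2", "y2"), 9606L)
  sig3 <- exclusive_intersections(list(A, A2))
  expect_equal(nrow(sig3), 1L)
  expect_equal(sig3$count, 2L)
  expect_equal(sig3$degree, 2L)

  dup <- list(A, A)
  expect_error(exclusive_intersections(dup), "duplicate")
})

test_that("exclusive intersections match per-key enumeration on random families", {
  for (seed in 1:10) {
    sets <- random_key_family(n_dbs = sample(2:6, 1), pool_size = 300,
                              seed = seed)
    got <- exclusive_intersections(sets)
    want <- oracle_exclusive(sets)
    expect_equal(sum(got$count), length(unique(unlist(sets))))
    expect_setequal(got$signature, names(want))
    for (s in got$signature) {
      expect_equal(got$count[got$signature == s], want[[s]])
    }
  }
})

test_that("shared_by_at_least spans union to intersection and is antitone", {
  A <- c("x", "y"); B <- c("y", "z"); C <- "y"
  sets <- list(A = A, B = B, C = C)
  expect_setequal(shared_by_at_least(sets, 1), c("x", "y", "z"))
  expect_equal(shared_by_at_least(sets, 2), "y")
  expect_equal(shared_by_at_least(sets, 3), "y")
  expect_error(shared_by_at_least(sets, 0), "between")
  expect_error(shared_by_at_least(sets, 4), "between")
  expect_length(shared_by_at_least(list(a = "p", b = "q"), 2), 0L)
  expect_length(shared_by_exactly(sets, 2), 0L)  # y is in all three
  expect_equal(shared_by_exactly(sets, 3), "y")
  expect_setequal(shared_by_exactly(sets, 1), c("x", "z"))

  for (seed in 1:5) {
    sets <- random_key_family(4, 200, seed)
    prev <- shared_by_at_least(sets, 1)
    for (k in 2:4) {
      cur <- shared_by_at_least(sets, k)
      expect_true(all(cur %in% prev))
      expect_identical(cur, oracle_shared_at_least(sets, k))
      prev <- cur
    }
  }
})

test_that("overlap coefficient is symmetric, bounded and 1 under containment", {
  A <- c("p", "q", "r", "s"); B <- c("r", "s", "t")
  expect_equal(overlap_coefficient(A, B), 2 / 3)
  expect_equal(overlap_coefficient(B, A), 2 / 3)
  expect_equal(overlap_coefficient(A, A), 1)
  expect_equal(overlap_coefficient(A, c("q", "r")), 1)  # subset
  expect_true(is.na(overlap_coefficient(A, character())))
})

test_that("overlap matrix has unit diagonal and the stated median", {
  sets <- list(A = c("1", "2", "3", "4"), B = c("1", "2"),
               C = c("1", "5", "6", "7"))
  m <- overlap_matrix(sets)
  expect_true(all(diag(m$values) == 1))
  expect_true(isSymmetric(m$values))
  expect_true(all(m$values >= 0 & m$values <= 1))
  # hand-computed coefficients 1.0 (A,B), 0.25 (A,C), 0.5 (B,C)
  expect_equal(m$values["A", "B"], 1)
  expect_equal(m$values["A", "C"], 0.25)
  expect_equal(m$values["B", "C"], 0.5)
  expect_equal(m$median_offdiag, 0.5)

  same <- overlap_matrix(list(X = c("a", "b"), Y = c("a", "b")))
  expect_true(all(same$values == 1))
  expect_equal(same$median_offdiag, 1)
})

test_that("overlap delta reports the max off-diagonal shift in percent", {
  sets <- list(A = c("1", "2", "3", "4"), B = c("1", "2"),
               C = c("1", "5", "6", "7"))
  m1 <- overlap_matrix(sets)
  expect_equal(overlap_delta(m1, m1), 0)
  m2 <- m1
  m2$values["A", "B"] <- m2$values["B", "A"] <- m1$values["A", "B"] - 0.03
  expect_equal(overlap_delta(m1, m2), 3)
  m3 <- overlap_matrix(list(X = "a", Y = "b"))
  expect_error(overlap_delta(m1, m3), "mismatch")
})

test_that("species protein counts tally distinct accessions per taxid", {
  keys <- snapshot_keys(ppi_snapshot("s", "A", "B", 9606L))
  expect_equal(species_protein_counts(keys)$n_proteins, 2L)

  self <- snapshot_keys(ppi_snapshot("s", "A", "A", 9606L))
  expect_equal(species_protein_counts(self)$n_proteins, 1L)

  # 3 pairs over 2 taxa, protein B shared between two human pairs:
  # human {A,B,C}, mouse {D,E}
  snap <- ppi_snapshot("s", c("A", "B", "D"), c("B", "C", "E"),
                       c(9606L, 9606L, 10090L))
  counts <- species_protein_counts(snapshot_keys(snap))
  expect_equal(counts$n_proteins[counts$taxid == 9606L], 3L)
  expect_equal(counts$n_proteins[counts$taxid == 10090L], 2L)
})
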