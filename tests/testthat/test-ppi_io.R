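mitab_line <- function(a, b, taxa = 9606L, taxb = taxa, type = "MI:0915") {
  paste(sprintf("uniprotkb:%s", a), sprintf("uniprotkb:%s", b),
        "-", "-", "-", "-", "-", "-", "-",
        sprintf("taxid:%d(human)", taxa), sprintf("taxid:%d(human)", taxb),
        sprintf('psi-mi:"%s"(association)', type),
        "-", "-", "-", sep = "\t")
}

test_that("MITAB reading canonicalizes, filters and counts malformed lines", {
  f <- tempfile(fileext = ".tsv")

  # same pair in both orders collapses to one record
  writeLines(c(mitab_line("P1", "P2"), mitab_line("P2", "P1"),
               mitab_line("P3", "P4")), f)
  snap <- read_mitab(f)
  expect_equal(nrow(snap$records), 2L)
  expect_true(all(snap$records$a <= snap$records$b))

  # interaction type outside the allow-list is dropped entirely
  writeLines(mitab_line("P1", "P2", type = "MI:0403"), f)
  expect_warning(empty <- read_mitab(f), "zero surviving")
  expect_equal(nrow(empty$records), 0L)
  expect_equal(empty$stats$n_filtered, 1L)

  # disabling the filter keeps it
  writeLines(mitab_line("P1", "P2", type = "MI:0403"), f)
  expect_equal(nrow(read_mitab(f, allowed_interaction_types = character())$records), 1L)

  # 10-line fixture with 2 malformed lines -> 8 records, malformed count 2
  good <- vapply(1:8, function(i) mitab_line(sprintf("A%d", i),
                                             sprintf("B%d", i)), "")
  writeLines(c(good[1:4], "uniprotkb:X\tuniprotkb:Y\tbroken",
               good[5:8], "justonefield"), f)
  snap <- read_mitab(f)
  expect_equal(nrow(snap$records), 8L)
  expect_equal(snap$stats$n_malformed, 2L)
})

test_that("MITAB cross-species and missing-taxid records are dropped and counted", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(mitab_line("P1", "P2", taxa = 9606L, taxb = 10090L),
               mitab_line("P3", "P4")), f)
  snap <- read_mitab(f)
  expect_equal(nrow(snap$records), 1L)
  expect_equal(snap$stats$n_cross_species, 1L)

  no_tax <- paste("uniprotkb:P5", "uniprotkb:P6", "-", "-", "-", "-", "-",
                  "-", "-", "-", "-", 'psi-mi:"MI:0915"(x)', "-", "-", "-",
                  sep = "\t")
  writeLines(c(no_tax, mitab_line("P3", "P4")), f)
  snap <- read_mitab(f)
  expect_equal(nrow(snap$records), 1L)
  expect_equal(snap$stats$n_no_taxid, 1L)
  snap <- read_mitab(f, default_taxid = 9606L)
  expect_equal(nrow(snap$records), 2L)
})

test_that("edge lists canonicalize, keep self-pairs and require a taxid", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA"), f)
  expect_equal(nrow(read_edgelist(f, taxid = 9606L)$records), 1L)

  writeLines("A\tA", f)
  snap <- read_edgelist(f, taxid = 9606L)
  expect_equal(snap$records$a, snap$records$b)
  expect_equal(nrow(snap$records), 1L)

  writeLines(c("A\tB\t9606", "C\tD\t9606", "E\tF\t9606", "A\tB\t9606",
               "G\tH\t9606"), f)
  expect_equal(nrow(read_edgelist(f)$records), 4L)

  writeLines("A\tB", f)
  expect_error(read_edgelist(f), "taxid")
})

test_that("edge-list round-trip reproduces the record-key set", {
  set.seed(11)
  snap <- ppi_snapshot("rt", sample(LETTERS, 40, TRUE),
                       sample(LETTERS, 40, TRUE),
                       sample(c(9606L, 10090L), 40, TRUE))
  f <- tempfile()
  write_edgelist(snap, f)
  back <- read_edgelist(f, name = "rt")
  expect_identical(snapshot_keys(back), snapshot_keys(snap))
})

test_that("accession normalization strips isoforms, maps secondaries and is idempotent", {
  snap <- ppi_snapshot("n", c("P12345-2", "secX", "Q99999"),
                       c("Q00001", "B1", "Q00001"), 9606L)
  map <- c(secX = "A0A000AAA1")
  norm <- normalize_accessions(snap, map)
  expect_true("P12345" %in% c(norm$records$a, norm$records$b))
  expect_true("A0A000AAA1" %in% c(norm$records$a, norm$records$b))
  # non-UniProt-shaped IDs with dashes stay intact
  snap2 <- ppi_snapshot("n2", "GENE-2", "B1", 9606L)
  norm2 <- normalize_accessions(snap2, map)
  expect_true("GENE-2" %in% c(norm2$records$a, norm2$records$b))
  # merging duplicates shrinks the snapshot
  snap3 <- ppi_snapshot("n3", c("P12345-2", "P12345"), c("Q00001", "Q00001"),
                        9606L)
  norm3 <- normalize_accessions(snap3, character())
  expect_equal(nrow(norm3$records), nrow(snap3$records) - 1L)
  # idempotent
  expect_identical(normalize_accessions(norm, map)$records, norm$records)
  expect_lte(nrow(norm$records), nrow(snap$records))
})

test_that("FASTA reading honours pipe headers, uppercases and warns on duplicates", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">sp|P1|NAME some description", "acdef",
               ">plain_header extra", "GHIKL"), f)
  seqs <- read_fasta(f)
  expect_named(seqs, c("P1", "plain_header"))
  expect_equal(seqs[["P1"]], "ACDEF")

  writeLines(c(">sp|P1|X", "AAA"), f)
  expect_equal(names(read_fasta(f, split_pipes = FALSE)), "sp|P1|X")

  writeLines(c(">D1", "AAA", ">D1", "CCC"), f)
  expect_warning(dups <- read_fasta(f), "duplicate")
  expect_equal(dups[["D1"]], "CCC")

  write_fasta(c(S1 = "MKV", S2 = "ACD"), f)
  expect_equal(read_fasta(f), c(S1 = "MKV", S2 = "ACD"))
})

test_that("PDB ensembles round-trip and mismatched models are rejected by name", {
  ens <- simulate_ensemble(n_models = 3L, n_res_a = 8L, n_res_b = 6L,
                           contact = list(res_a = 4L, res_b = 3L, frac = 1 / 3,
                                          near = 5, far = 30),
                           seed = 5L)$ensemble
  f <- tempfile(fileext = ".pdb")
  write_pdb_ensemble(ens, f)
  back <- read_pdb_ensemble(f)
  expect_equal(n_models(back), 3L)
  expect_equal(back$chain, ens$chain)
  expect_equal(back$resno, ens$resno)
  expect_equal(back$coords, ens$coords, tolerance = 1e-3)

  # single-model file without MODEL records
  lines <- readLines(f)
  atoms <- lines[startsWith(lines, "ATOM")]
  writeLines(atoms[1:14], f)
  one <- read_pdb_ensemble(f)
  expect_equal(n_models(one), 1L)
  expect_equal(dim(one$coords)[2L], 14L)

  # model 2 lacking one residue is an error naming the mismatch
  write_pdb_ensemble(ens, f)
  lines <- readLines(f)
  drop <- which(startsWith(lines, "ATOM"))[20L]
  writeLines(lines[-drop], f)
  expect_error(read_pdb_ensemble(f), "mismatch")
})
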