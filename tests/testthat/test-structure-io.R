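test_that("PDB round trip preserves coordinates to fixed-width precision", {
  h <- generate_helix(40)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ca_pdb(h, f)
  tr <- read_ca_trace(f)
  expect_equal(tr$length, 40L)
  expect_equal(tr$coords, h$coords, tolerance = 1e-3)
  expect_equal(tr$residue_ids, 1:40)

  w <- random_walk_trace(25, seed = 2)
  write_ca_pdb(w, f)
  expect_equal(suppressWarnings(read_ca_trace(f))$coords, w$coords,
               tolerance = 1e-3)
})

test_that("reading respects chain selection and file order", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:3, c(5L, 9L, 10L), c(0, 3.8, 7.6), 0, 0),
    sprintf("ATOM  %5d  CA  ALA B%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            4:5, 1:2, c(50, 53.8), 0, 0),
    "END")
  writeLines(lines, f)
  tr <- read_ca_trace(f)  # first chain with C-alphas
  expect_equal(tr$chain, "A")
  expect_equal(tr$length, 3L)
  expect_equal(tr$residue_ids, c(5L, 9L, 10L))  # non-contiguous, file order
  expect_equal(tr$coords[, 1], c(0, 3.8, 7.6))

  trb <- read_ca_trace(f, chain = "B")
  expect_equal(trb$length, 2L)
  expect_error(read_ca_trace(f, chain = "Z"), "chain not found")
})

test_that("only the first model is read and altloc B is dropped", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:3, 1:3, c(0, 3.8, 7.6), 0, 0),
    "ENDMDL",
    "MODEL        2",
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:3, 1:3, c(100, 103.8, 107.6), 0, 0),
    "ENDMDL",
    "END"), f)
  tr <- read_ca_trace(f)
  expect_equal(tr$length, 3L)
  expect_equal(tr$coords[, 1], c(0, 3.8, 7.6))

  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END"), f)
  tr <- read_ca_trace(f)
  expect_equal(tr$length, 2L)
  expect_equal(tr$coords[1, 1], 0)  # altloc A kept, B dropped
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(read_ca_trace(file.path(tempdir(), "nope.pdb")), "unreadable")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "END"), f)
  expect_error(read_ca_trace(f), "empty trace")
})

test_that("chain breaks are reported but the trace is kept whole", {
  h <- generate_helix(20)
  h$coords[11:20, ] <- h$coords[11:20, ] + c(30, 0, 0)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ca_pdb(ca_trace("broken", h$coords), f)
  expect_warning(tr <- read_ca_trace(f), "chain break")
  expect_equal(tr$length, 20L)
})

test_that("report tables are sorted by z and degenerate rows survive", {
  h <- generate_helix(60)
  p <- perturb_trace(h, 0.5, seed = 1)
  d <- random_walk_trace(60, seed = 2)
  r1 <- align_structures(h, p)
  r2 <- align_structures(h, d)
  stub <- align_structures(generate_helix(2), generate_helix(2))  # too short
  f <- withr::local_tempfile(fileext = ".tsv")

  write_report_table(list(), f)
  empty <- read.delim(f)
  expect_equal(nrow(empty), 0L)
  expect_equal(names(empty),
               c("target_id", "db_id", "L_Q", "L_P", "Ne", "cRMSD",
                 "RMSD100", "TM_score", "PSI", "z_score", "flags"))

  write_report_table(list(r2, stub, r1), f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$db_id[1], r1$db_id)  # highest z first
  expect_true(all(diff(ifelse(is.na(tab$z_score), -Inf, tab$z_score)) <= 0))
  stub_row <- tab[tab$Ne == 0, ]
  expect_equal(nrow(stub_row), 1L)
  expect_true(grepl("no_alignment", stub_row$flags))
  expect_true(is.na(stub_row$cRMSD))
})

test_that("pair alignment files list residue ids and zero self distances", {
  h <- generate_helix(5)
  # self alignment of a 5-residue trace goes through the residue-only path
  rep <- align_structures(h, h)
  f <- withr::local_tempfile(fileext = ".txt")
  write_pair_alignment(rep, h, h, f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 5L)
  parts <- do.call(rbind, strsplit(body, "\t"))
  expect_equal(as.integer(parts[, 1]), 1:5)
  expect_equal(parts[, 3], rep("0.000", 5))

  empty <- align_structures(generate_helix(2), generate_helix(2))
  write_pair_alignment(empty, generate_helix(2), generate_helix(2), f)
  expect_true(all(startsWith(readLines(f), "#")))
})
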