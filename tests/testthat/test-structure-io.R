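# PDB reading/writing and segment selection with renumbering.

test_that("minimal and multi-model PDB files parse with correct counts", {
  f <- write_tmp_pdb(c(
    pdb_line(1, "CA", "LEU", "A", 1, 1, 2, 3),
    pdb_line(2, "CA", "LEU", "A", 2, 2, 3, 4)))
  m <- read_structure(f)
  expect_length(m, 1)
  expect_equal(nrow(m[[1]]$atoms), 2)

  blocks <- unlist(lapply(1:5, function(k) {
    c(sprintf("MODEL %8d", k),
      pdb_line(1, "CA", "LEU", "A", 1, k, 0, 0),
      pdb_line(2, "CA", "LEU", "A", 2, k, 1, 0),
      "ENDMDL")
  }))
  f5 <- write_tmp_pdb(blocks)
  expect_length(read_structure(f5), 5)
})

test_that("malformed inputs are rejected", {
  expect_error(read_structure(tempfile()), "I/O error")
  f_het <- write_tmp_pdb(pdb_line(1, "P", "POP", "U", 1, 0, 0, 0,
                                  record = "HETATM"))
  expect_error(read_structure(f_het), "no ATOM records")
  # insertion code in column 27
  l <- pdb_line(1, "CA", "LEU", "A", 1, 0, 0, 0)
  substr(l, 27, 27) <- "A"
  expect_error(read_structure(write_tmp_pdb(c(
    l, pdb_line(2, "CA", "LEU", "A", 2, 1, 1, 1)))), "insertion")
  # duplicate atom key within a model
  expect_error(read_structure(write_tmp_pdb(c(
    pdb_line(1, "CA", "LEU", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "LEU", "A", 1, 1, 1, 1)))), "duplicate")
})

test_that("write/read round trip preserves labels, coordinates and models", {
  models <- list(tiny_dimer(-30), tiny_dimer(-10), tiny_dimer(40))
  f <- tempfile(fileext = ".pdb")
  write_structure(models, f)
  expect_equal(sum(grepl("^MODEL", readLines(f))), 3)
  back <- read_structure(f)
  expect_length(back, 3)
  for (k in 1:3) {
    expect_identical(back[[k]]$atoms[, c("chain", "resno", "resid", "elety")],
                     models[[k]]$atoms[, c("chain", "resno", "resid", "elety")])
    expect_lt(max(abs(as.matrix(back[[k]]$atoms[, c("x", "y", "z")]) -
                        as.matrix(models[[k]]$atoms[, c("x", "y", "z")]))),
              1e-3)
  }
  # HETATM pseudo-atoms survive the round trip under their residue names
  slab <- slab_as_model(make_membrane_slab())
  combined <- structure_model(rbind(models[[1]]$atoms, slab$atoms))
  f2 <- tempfile(fileext = ".pdb")
  write_structure(combined, f2)
  b2 <- read_structure(f2)[[1]]
  expect_equal(sum(b2$atoms$resid == "POP"), 144)
  expect_true(all(b2$atoms$type[b2$atoms$resid == "POP"] == "HETATM"))
})

test_that("label overflow is a format error", {
  m <- tiny_dimer()
  m$atoms$chain[1] <- "AB"
  expect_error(write_structure(m, tempfile(fileext = ".pdb")),
               "chain id")
})

test_that("select_segment renumbers to start at 1 and validates input", {
  h <- make_ideal_helix(30)
  seg <- helix_segment("A", 6, 29)
  ca <- select_segment(h, seg, "CA")
  expect_equal(nrow(ca), 24)
  expect_equal(ca$resno, 1:24)
  expect_equal(ca$resno_orig, 6:29)
  bb <- select_segment(h, seg, "backbone")
  expect_equal(nrow(bb), 24 * 4)
  expect_setequal(unique(bb$elety), c("N", "CA", "C", "O"))
  expect_error(select_segment(h, helix_segment("B", 1, 10), "CA"),
               "chain 'B'")
  expect_error(select_segment(h, helix_segment("A", 25, 40), "CA"),
               "residue")
  # named atom filter
  hx <- select_segment(make_ideal_helix(10, sequence = "S"),
                       helix_segment("A", 1, 10), "OG")
  expect_equal(nrow(hx), 10)
})

test_that("amide-H reconstruction is geometric and idempotent", {
  h <- make_ideal_helix(12)
  again <- reconstruct_amide_h(h)
  expect_identical(again$atoms, h$atoms)  # H already present
  stripped <- structure_model(h$atoms[h$atoms$elety != "H", ])
  rebuilt <- reconstruct_amide_h(stripped)
  hb <- rebuilt$atoms[rebuilt$atoms$elety == "H", ]
  h0 <- h$atoms[h$atoms$elety == "H" & h$atoms$resno > 1, ]
  expect_equal(nrow(hb), nrow(h0))  # chain-initial residue has no C(prev)
  dist <- sqrt(rowSums((as.matrix(hb[, c("x", "y", "z")]) -
                          as.matrix(h0[, c("x", "y", "z")]))^2))
  expect_lt(max(dist), 0.15)
})

test_that("trajectory container enforces labeling and time ordering", {
  h <- make_ideal_helix(10)
  expect_error(trajectory(list(h, h), times_ns = c(0, 0)),
               "strictly increasing")
  h2 <- h; h2$atoms <- h2$atoms[rev(seq_len(nrow(h2$atoms))), ]
  expect_error(trajectory(list(h, structure_model(h2$atoms)), c(0, 1)),
               "labeling")
  tr <- trajectory(list(h, h), c(0, 1))
  expect_equal(n_frames(tr), 2)
  expect_equal(frame_model(tr, 2)$atoms$x, h$atoms$x)
})
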