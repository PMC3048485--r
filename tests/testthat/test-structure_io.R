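test_that("read_pdb_calpha reads residues in file order, ignoring side chains and HETATM", {
  txt <- pdb_text(
    atom_line(1, "N",  "LYS", "A", 1, 0.1, 0.2, 0.3),
    atom_line(2, "CA", "LYS", "A", 1, 1, 0, 0),
    atom_line(3, "CB", "LYS", "A", 1, 1.5, 0.5, 0),
    atom_line(4, "CA", "GLU", "A", 2, -1, 0, 0),
    atom_line(5, "CA", "GLY", "A", 3, 0, 2, 0),
    atom_line(6, "O",  "HOH", "A", 101, 9, 9, 9, record = "HETATM"),
    atom_line(7, "ZN", "ZN",  "A", 102, 8, 8, 8, record = "HETATM", element = "ZN")
  )
  ch <- read_pdb_calpha(txt)
  expect_length(ch, 1)
  st <- ch[[1]]
  expect_equal(st$resname, c("LYS", "GLU", "GLY"))
  expect_equal(st$x, c(1, -1, 0))
  expect_equal(attr(st, "n_missing_ca"), 0)
})

test_that("altloc keeps the highest-occupancy conformer; ties go to first in file", {
  txt <- pdb_text(
    atom_line(1, "CA", "SER", "A", 1, 1, 0, 0, altloc = "A", occ = 0.4),
    atom_line(2, "CA", "SER", "A", 1, 2, 0, 0, altloc = "B", occ = 0.6),
    atom_line(3, "CA", "THR", "A", 2, 3, 0, 0, altloc = "A", occ = 0.5),
    atom_line(4, "CA", "THR", "A", 2, 4, 0, 0, altloc = "B", occ = 0.5)
  )
  st <- read_pdb_calpha(txt)[[1]]
  expect_equal(st$x, c(2, 3))
})

test_that("residues lacking a Calpha are skipped and tallied", {
  txt <- pdb_text(
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    atom_line(2, "CA", "ALA", "A", 2, 1, 0, 0),
    atom_line(3, "N",  "GLY", "A", 3, 2, 0, 0),  # no CA
    atom_line(4, "CA", "ALA", "A", 4, 3, 0, 0),
    atom_line(5, "CA", "ALA", "A", 5, 4, 0, 0)
  )
  expect_warning(ch <- read_pdb_calpha(txt), "lacking a C-alpha")
  expect_equal(nrow(ch[[1]]), 4)
  expect_equal(attr(ch[[1]], "n_missing_ca"), 1)
})

test_that("first MODEL only; chain and residue-range selection; error paths", {
  txt <- pdb_text(
    "MODEL        1",
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    atom_line(2, "CA", "ALA", "A", 2, 1, 0, 0),
    atom_line(3, "CA", "GLY", "B", 1, 5, 0, 0),
    "ENDMDL",
    "MODEL        2",
    atom_line(4, "CA", "ALA", "A", 1, 99, 0, 0),
    "ENDMDL"
  )
  ch <- read_pdb_calpha(txt)
  expect_named(ch, c("A", "B"))
  expect_equal(ch$A$x, c(0, 1))
  only_a <- read_pdb_calpha(txt, chains = "A", residue_range = c(2, 2))
  expect_equal(only_a$A$resseq, 2L)
  expect_error(read_pdb_calpha(txt, residue_range = c(1, 2)),
               "exactly one chain")
  expect_error(read_pdb_calpha(txt, chains = "Z"), "no protein residues")
  bad <- pdb_text(atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0))
  substr(bad, 32, 35) <- "abcd"
  expect_error(read_pdb_calpha(bad), "line 1")
})

test_that("insertion codes are part of residue identity", {
  txt <- pdb_text(
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    atom_line(2, "CA", "GLY", "A", 1, 1, 0, 0, icode = "A"),
    atom_line(3, "CA", "SER", "A", 2, 2, 0, 0)
  )
  st <- read_pdb_calpha(txt)[[1]]
  expect_equal(nrow(st), 3)
  expect_equal(st$icode, c(" ", "A", " "))
})

test_that("detect_rna_chains uses the >50% ribonucleotide rule, never DNA", {
  rna <- sapply(1:4, function(i)
    atom_line(i, "P", c("A", "U", "G", "C")[i], "R", i, i, 0, 0, element = "P"))
  dna <- sapply(1:4, function(i)
    atom_line(4 + i, "P", c("DA", "DT", "DG", "DC")[i], "D", i, i, 5, 0, element = "P"))
  mix <- sapply(1:5, function(i)
    atom_line(8 + i, "C1", c("U", "U", "U", "XXX", "YYY")[i], "M", i, i, 9, 0))
  prot <- atom_line(14, "CA", "ALA", "P", 1, 0, 0, 9)
  txt <- pdb_text(rna, dna, mix, prot)
  expect_setequal(detect_rna_chains(txt), c("R", "M"))
})

test_that("count_contact_residues matches a brute-force scan and handles constructed cases", {
  # protein far away -> 0 contacts
  far_p <- data.frame(chain = "P", resseq = 1:3, icode = " ",
                      resname = "ALA", name = "CA",
                      x = 100 + (1:3), y = 0, z = 0)
  rna <- data.frame(x = c(0, 1), y = 0, z = 0)
  expect_equal(count_contact_residues(far_p, rna, cutoff = 4.5), 0)
  # exactly 3 residues placed at cutoff - 0.1
  near <- data.frame(chain = "P", resseq = 1:5, icode = " ",
                     resname = "ALA", name = "CA",
                     x = c(4.4, 4.4, 4.4, 50, 60), y = 0, z = 0)
  expect_equal(count_contact_residues(near, data.frame(x = 0, y = 0, z = 0),
                                      cutoff = 4.5), 3)
  # random complex vs exhaustive double loop
  set.seed(42)
  for (rep in 1:5) {
    np <- 40; nr <- 25
    p <- data.frame(chain = "P", resseq = sample(1:15, np, replace = TRUE),
                    icode = " ", resname = "ALA", name = "X",
                    x = runif(np, 0, 20), y = runif(np, 0, 20),
                    z = runif(np, 0, 20))
    r <- data.frame(x = runif(nr, 0, 20), y = runif(nr, 0, 20),
                    z = runif(nr, 0, 20))
    cutoff <- 5
    hit_res <- unique(p$resseq[sapply(seq_len(np), function(i) {
      any(sqrt((p$x[i] - r$x)^2 + (p$y[i] - r$y)^2 + (p$z[i] - r$z)^2) <= cutoff)
    })])
    expect_equal(count_contact_residues(p, r, cutoff), length(hit_res))
  }
  expect_error(count_contact_residues(near[0, ], rna), "read_pdb_heavy_atoms")
})

test_that("contact count is invariant under a joint rigid transformation", {
  set.seed(7)
  p <- data.frame(chain = "P", resseq = 1:30, icode = " ", resname = "ALA",
                  name = "X", x = runif(30, 0, 20), y = runif(30, 0, 20),
                  z = runif(30, 0, 20))
  r <- data.frame(x = runif(20, 0, 20), y = runif(20, 0, 20),
                  z = runif(20, 0, 20))
  before <- count_contact_residues(p, r, 6)
  rot <- random_rotation(); shift <- c(3, -8, 12)
  tp <- as.matrix(p[, c("x", "y", "z")]) %*% t(rot)
  tr <- as.matrix(r) %*% t(rot)
  p2 <- p; p2[, c("x", "y", "z")] <- sweep(tp, 2, shift, "+")
  r2 <- as.data.frame(sweep(tr, 2, shift, "+")); names(r2) <- c("x", "y", "z")
  expect_equal(count_contact_residues(p2, r2, 6), before)
})

test_that("write_minimal_pdb round-trips names and coordinates to 1e-3 A", {
  expect_error(write_minimal_pdb(list()), "non-empty")
  expect_error(write_minimal_pdb(list(A = data.frame(
    resname = "GLY", x = 1e5, y = 0, z = 0))), "column width")
  set.seed(11)
  n <- 100
  df <- data.frame(resname = sample(c("LYS", "GLU", "GLY"), n, replace = TRUE),
                   x = runif(n, -99, 99), y = runif(n, -99, 99),
                   z = runif(n, -99, 99))
  txt <- write_minimal_pdb(list(Q = df))
  st <- read_pdb_calpha(txt)[[1]]
  expect_equal(nrow(st), n)
  expect_equal(st$resname, df$resname)
  expect_lt(max(abs(as.matrix(st[, c("x", "y", "z")]) -
                    as.matrix(df[, c("x", "y", "z")]))), 1e-3 + 1e-12)
})
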