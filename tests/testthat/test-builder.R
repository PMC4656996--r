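test_that("protein charges follow the Lys/His/Arg +, Asp/Glu - rule", {
  dm <- domain_map("NTD", 1, 4, folded = FALSE)
  topo <- build_protein_topology("KKDE", dm)
  expect_equal(topo$beads$charge, c(1, 1, -1, -1))
  dm2 <- domain_map("NTD", 1, 6, folded = FALSE)
  topo2 <- build_protein_topology("KHRDEA", dm2)
  expect_equal(topo2$beads$charge, c(1, 1, 1, -1, -1, 0))
})

test_that("CTD neutralization zeroes exactly the CTD lysines", {
  aa <- rep("A", 393)
  k_ctd <- c(370, 372, 373, 381, 382, 386)  # six CTD lysines
  aa[k_ctd] <- "K"
  aa[c(10, 120)] <- "K"                      # lysines outside the CTD
  core <- p53cg:::.helix_coords(199)
  tet <- p53cg:::.helix_coords(31, origin = c(60, 0, 0))
  topo <- build_protein_topology(paste(aa, collapse = ""), p53_domain_map(),
                                 native_coords = list(Core = core, TET = tet),
                                 neutralize_ctd = TRUE)
  expect_equal(sum(topo$beads$charge[357:393]), 0)
  expect_equal(unname(topo$beads$charge[c(10, 120)]), c(1, 1))
  topo0 <- build_protein_topology(paste(aa, collapse = ""), p53_domain_map(),
                                  native_coords = list(Core = core,
                                                       TET = tet))
  expect_equal(sum(topo0$beads$charge[357:393]), 6)
})

test_that("a folded toy helix gets one bead per residue and chain bonds", {
  dm <- domain_map("Core", 1, 10, folded = TRUE)
  xyz <- p53cg:::.helix_coords(10)
  topo <- build_protein_topology("AAAAAAAAAA", dm,
                                 native_coords = list(Core = xyz))
  expect_equal(n_beads(topo), 10)
  expect_equal(nrow(topo$bonds), 9)
  expect_true(all(topo$bonds$cat == "folded"))
  expect_true(all(abs(topo$bonds$r0 - 3.8) < 0.3))
})

test_that("missing native coordinates or length mismatch are errors", {
  dm <- domain_map("Core", 1, 10, folded = TRUE)
  expect_error(build_protein_topology("AAAAAAAAAA", dm), "native coordinates")
  expect_error(build_protein_topology("AAAA", dm), "length")
})

test_that("p53 domain map partitions residues 1..393", {
  dm <- p53_domain_map()
  lab <- p53cg:::.domain_of(dm, 1:393)
  expect_true(all(nzchar(lab)))
  expect_equal(sum(lab == "NTD"), 90)
  expect_equal(sum(lab == "Core"), 199)
  expect_equal(sum(lab == "Linker"), 36)
  expect_equal(sum(lab == "TET"), 31)
  expect_equal(sum(lab == "CTD"), 37)
})

test_that("duplex bead and phosphate counts follow the 5'-omission rule", {
  seqd <- p53cg:::re_sequence(100)
  topo <- build_dna_topology(seqd)
  expect_equal(n_beads(topo), 2 * (100 + 100 + 99))
  expect_equal(sum(topo$beads$kind == "P"), 198)
  expect_equal(total_charge(topo), -198)
  expect_true(all(topo$beads$charge[topo$beads$kind == "P"] == -1))
})

test_that("a single-nucleotide strand has sugar and base beads only", {
  topo <- build_dna_topology("A", duplex = FALSE)
  expect_equal(n_beads(topo), 2)
  expect_equal(sort(topo$beads$kind), c("B", "S"))
  expect_equal(sum(topo$beads$kind == "P"), 0)
})

test_that("RE annotation places half-sites and quarters correctly", {
  re <- annotate_re(50, re_start = 11, spacer = 0)
  expect_equal(re$half_site1, c(11, 20))
  expect_equal(re$half_site2, c(21, 30))
  expect_equal(re$quarters[[1]], c(11, 15))
  expect_equal(re$quarters[[4]], c(26, 30))
  re2 <- annotate_re(50, re_start = 11, spacer = 2)
  expect_equal(re2$half_site2, c(23, 32))
  expect_error(annotate_re(25, re_start = 11, spacer = 0), "fit")
  # consensus validation
  expect_silent(annotate_re(50, 11, 0, sequence = p53cg:::re_sequence(50)))
  bad <- p53cg:::re_sequence(50)
  substr(bad, 14, 14) <- "A"   # breaks the invariant C at position 4
  expect_error(annotate_re(50, 11, 0, sequence = bad), "RRRCWWGYYY")
})

test_that("ideal B-DNA geometry has the B-form rise and helical repeat", {
  x2 <- ideal_bdna_coords(2)
  topo2 <- build_dna_topology("AT")
  s2 <- dna_sugar_indices(topo2, 1)
  expect_equal(x2[s2[2], 3] - x2[s2[1], 3], 3.38)
  topo11 <- build_dna_topology(p53cg:::re_sequence(30))
  s <- dna_sugar_indices(topo11, 1)
  x <- topo11$coords
  u <- x[s[11], ] - x[s[1], ]           # one full turn
  expect_equal(u[1], 0, tolerance = 1e-10)
  expect_equal(u[2], 0, tolerance = 1e-10)
  expect_equal(u[3], 33.8, tolerance = 1e-10)
  expect_identical(ideal_bdna_coords(17), ideal_bdna_coords(17))
  expect_error(ideal_bdna_coords(1), ">= 2")
})

test_that("native contact map applies cutoff and sequence separation", {
  collinear <- cbind(10 * (0:2), 0, 0)
  expect_equal(nrow(native_contact_map(collinear, 6.5, 3)), 0)
  # 5 beads all within the cutoff of each other
  compact <- rbind(c(0, 0, 0), c(3, 0, 0), c(1.5, 2.6, 0), c(1.5, 0.9, 2.5),
                   c(1.5, 1.2, -2.4))
  cm <- native_contact_map(compact, cutoff = 6.5, min_seq_sep = 3)
  expect_equal(nrow(cm), 3)
  expect_equal(unname(as.matrix(cm[, c("i", "j")])),
               rbind(c(1L, 4L), c(1L, 5L), c(2L, 5L)))
  expect_true(all(cm$r0 > 0))
  expect_error(native_contact_map(compact, cutoff = -1), "positive")
})

test_that("contact map of a structure against itself gives Q = 1", {
  xyz <- p53cg:::.helix_coords(20)
  cm <- native_contact_map(xyz, 6.5, 4)
  expect_gt(nrow(cm), 0)
  expect_equal(qscore(xyz, cm), 1.0)
})

test_that("charge bookkeeping is exact on a combined system", {
  fx <- make_toy_fixture("mini_core_dna", seed = 2)
  b <- fx$topology$beads
  expected <- sum(b$name %in% c("K", "H", "R") & b$kind == "CA") -
    sum(b$name %in% c("D", "E") & b$kind == "CA") -
    sum(b$kind == "P")
  expect_equal(total_charge(fx$topology), expected)
})

test_that("toy fixtures are reproducible and self-consistent", {
  f1 <- make_toy_fixture("tetramer_toy", seed = 9)
  f2 <- make_toy_fixture("tetramer_toy", seed = 9)
  expect_identical(f1$coords, f2$coords)
  expect_identical(f1$topology$contacts, f2$topology$contacts)
  # reference pose is native for every Core
  for (s in 1:4)
    expect_equal(qscore(f1$coords, f1$core_contacts[[s]]), 1.0)
  # mini fixture: native self-consistency
  m <- make_toy_fixture("mini_core_dna", seed = 4)
  expect_equal(qscore(m$coords, m$core_contacts[[1]]), 1.0)
  # downstream classification of the constructed pairing is a valid type
  ty <- classify_frame(f1$coords, f1$core_beads, f1$quarter_beads,
                       f1$tet_partner)
  expect_true(ty$type %in% 1:3)
  expect_error(make_toy_fixture("tetramer_toy", params = list(core_n = 2)),
               "degenerate")
})
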