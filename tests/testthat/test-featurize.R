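test_that("sequence features encode the amino-acid change and topology", {
  seq <- fixture_seq()
  topo <- fixture_topo()
  labels <- c(format_hgvs_p(216, seq$residues[216], "L"),
              format_hgvs_p(471, seq$residues[471], "C"))
  # construct variants whose chemistry we control: use synthetic sequence
  s2 <- protein_sequence(c("M", "R", "G", "V", "P"))
  t2 <- topology_map(data.frame(name = c("N-term", "TM1", "C-term"),
                                class = c("N-term", "TM", "C-term"),
                                start = c(1, 2, 4), end = c(1, 3, 5)))
  v <- parse_hgvs_p(c("p.R2C", "p.V4L", "p.G3W", "p.V4P"))
  x <- sequence_features(v, s2, t2)
  expect_equal(unname(x["p.R2C", "d_charge"]), -1)  # Arg(+1) -> Cys(0)
  expect_equal(unname(x["p.V4L", "d_charge"]), 0)   # both neutral
  expect_equal(unname(x["p.R2C", "class_TM"]), 1)
  expect_equal(unname(x["p.V4L", "class_TM"]), 0)
  expect_equal(unname(x["p.V4L", "class_Cterm"]), 1)
  expect_equal(unname(x["p.G3W", "glycine_removed"]), 1)
  expect_equal(unname(x["p.V4P", "proline_introduced"]), 1)
  expect_equal(unname(x["p.V4L", "d_hydropathy"]),
               unname(aa_hydropathy["L"] - aa_hydropathy["V"]))
  expect_equal(unname(x["p.G3W", "d_volume"]),
               unname(aa_volume["W"] - aa_volume["G"]))
  expect_equal(unname(x["p.R2C", "position"]), 2)

  # region indicators agree with region_of on the packaged map
  v557 <- parse_hgvs_p(labels)
  xf <- sequence_features(v557, seq, topo)
  reg <- region_of(v557$pos, topo)
  for (i in seq_len(nrow(v557))) {
    expect_equal(unname(xf[i, paste0("region_", reg$name[i])]), 1)
    expect_equal(sum(xf[i, startsWith(colnames(xf), "region_")]), 1)
    expect_equal(sum(xf[i, startsWith(colnames(xf), "class_")]), 1)
  }

  # deterministic and order-independent
  x2 <- sequence_features(v[c(3, 1, 4, 2), ], s2, t2)
  expect_equal(x2[rownames(x), ], x)
})

test_that("structure features match a brute-force contact oracle", {
  model <- synthetic_helix(30, plddt = seq(60, 89))
  v <- data.frame(label = paste0("v", 1:30), pos = 1:30)
  x <- structure_features(v, model, radius = 10)
  # O(n^2) all-pairs oracle
  d <- as.matrix(dist(model$coords))
  oracle <- rowSums(d <= 10) - 1L
  expect_equal(unname(x[, "contact_number"]), unname(oracle))
  expect_equal(unname(x[, "rel_burial"]),
               unname(oracle / max(oracle)))
  # pLDDT is a pass-through of the stored confidence
  expect_equal(unname(x[, "plddt"]), seq(60, 89))

  # a residue far from everything has contact number 0 and burial 0
  coords <- rbind(model$coords, c(1000, 1000, 1000))
  m2 <- structure_model(coords, c(model$plddt, 50))
  x2 <- structure_features(data.frame(label = "far", pos = 31L), m2)
  expect_equal(unname(x2[, "contact_number"]), 0)
  expect_equal(unname(x2[, "rel_burial"]), 0)

  # missing coordinates yield missing features
  coords[5, ] <- NA
  m3 <- structure_model(coords, c(model$plddt, 50))
  x3 <- structure_features(data.frame(label = "v5", pos = 5L), m3)
  expect_true(is.na(x3[, "contact_number"]))
})

test_that("PDB reading recovers coordinates and B-factor confidence", {
  model <- synthetic_helix(12, plddt = round(seq(70, 92), 2)[1:12])
  pdb <- tempfile(fileext = ".pdb")
  lines <- vapply(1:12, function(i) {
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00%6.2f           C",
            i, i, model$coords[i, 1], model$coords[i, 2],
            model$coords[i, 3], model$plddt[i])
  }, character(1))
  writeLines(c(lines, "END"), pdb)
  got <- read_structure_pdb(pdb)
  expect_equal(got$coords, model$coords, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(got$plddt, model$plddt, tolerance = 1e-2)
})

test_that("prediction features join score tables with missingness policy", {
  v <- data.frame(label = c("p.A1G", "p.A2G", "p.A3G"))
  t1 <- data.frame(variant = c("p.A1G", "p.A3G"), score = c(0.9, 0.1))
  t2 <- data.frame(variant = c("p.A2G"), score = c(0.5))
  x <- prediction_features(v, list(s1 = t1, s2 = t2))
  expect_equal(unname(x[, "s1"]), c(0.9, NA, 0.1))
  expect_equal(unname(x[, "s2"]), c(NA, 0.5, NA))
  # missingness pattern is the set complement of each table's keys
  expect_equal(is.na(x[, "s1"]), !(v$label %in% t1$variant),
               ignore_attr = TRUE)
  dup <- rbind(t1, t1[1, ])
  expect_error(prediction_features(v, list(s1 = dup)), "duplicate")
})

test_that("0-1 scaling stores parameters, imputes, clips and reports constants", {
  x <- cbind(a = c(2, 4, 6, 10), b = c(1, 1, 1, 1), c = c(0.5, NA, 1.5, 2.5))
  sc <- fit_feature_scaling(x)
  xs <- scale_features(x, sc)
  expect_equal(unname(xs[, "a"]), c(0, 0.25, 0.5, 1))
  expect_true(all(xs[, "b"] == 0))       # constant column scales to 0
  expect_equal(sc$constant, "b")
  # NA imputed at the training mean then scaled, indicator set
  expect_equal(unname(xs[, "c_missing"]), c(0, 1, 0, 0))
  expect_equal(unname(xs[2, "c"]), (1.5 - 0.5) / 2)  # mean 1.5, range 0.5..2.5
  # training rows span [0, 1] exactly for non-constant columns
  expect_equal(range(xs[, "a"]), c(0, 1))
  # new rows outside the training range are clipped
  xnew <- cbind(a = c(-5, 100), b = c(0, 9), c = c(NA, 3.5))
  xns <- scale_features(xnew, sc)
  expect_equal(unname(xns[, "a"]), c(0, 1))
  expect_equal(unname(xns[, "c_missing"]), c(1, 0))
  # inverse transform recovers raw training values to machine precision
  back <- xs[, "a"] * (sc$max["a"] - sc$min["a"]) + sc$min["a"]
  expect_equal(unname(back), x[, "a"], ignore_attr = TRUE)
  # applying unfitted scaling or mismatched columns is an error
  expect_error(scale_features(x, list()), "not been fitted")
  expect_error(scale_features(x[, c(2, 1, 3)], sc), "do not match")
})

test_that("feature assembly restricts to the requested feature set", {
  st <- smoke_study(seed = 5)
  v <- st$variants
  xs <- assemble_features(v, st$seq, st$topo, feature_set = "sequence")
  expect_true("d_hydropathy" %in% colnames(xs))
  expect_false("plddt" %in% colnames(xs))
  xa <- assemble_features(v, st$seq, st$topo, st$structure,
                          st$score_tables, feature_set = "all")
  expect_true(all(c("d_hydropathy", "plddt", names(st$score_tables)) %in%
                    colnames(xa)))
  expect_error(assemble_features(v, feature_set = "sequence"), "requires")
  expect_error(assemble_features(v, st$seq, st$topo,
                                 feature_set = "structure"), "requires")
})
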