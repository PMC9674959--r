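test_that("HGVS-p parsing extracts components and round-trips", {
  v <- parse_hgvs_p("p.V216L")
  expect_equal(v$pos, 216L)
  expect_equal(v$ref, "V")
  expect_equal(v$alt, "L")
  expect_equal(v$label, "p.V216L")

  # exhaustive round-trip over all ref/alt pairs at a spread of positions
  pairs <- expand.grid(ref = aa_alphabet, alt = aa_alphabet,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  for (pos in c(1L, 57L, 557L)) {
    labels <- format_hgvs_p(pos, pairs$ref, pairs$alt)
    parsed <- parse_hgvs_p(labels)
    expect_identical(parsed$label, labels)
    expect_identical(parsed$ref, pairs$ref)
    expect_identical(parsed$alt, pairs$alt)
    expect_true(all(parsed$pos == pos))
  }
})

test_that("HGVS-p parsing rejects malformed, synonymous and non-canonical labels", {
  expect_error(parse_hgvs_p("V216L"), "malformed")
  expect_error(parse_hgvs_p("p.V216"), "malformed")
  expect_error(parse_hgvs_p("p.Val216Leu"), "malformed")
  expect_error(parse_hgvs_p("p.V216V"), "synonymous")
  expect_error(parse_hgvs_p("p.B216L"), "non-canonical")
  expect_error(parse_hgvs_p("p.V216X"), "non-canonical")
})

test_that("protein sequences validate their alphabet and FASTA reading works", {
  expect_error(protein_sequence("ACDXF"), "non-canonical")
  expect_error(protein_sequence(character(0)), "at least one")
  seq <- fixture_seq()
  expect_s3_class(seq, "protein_sequence")
  expect_equal(length(seq), 557L)

  multi <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEF", ">b", "GHIKL"), multi)
  expect_error(read_protein_fasta(multi), "records")
  expect_equal(read_protein_fasta(multi, id = "b")$residues,
               c("G", "H", "I", "K", "L"))
})

test_that("variant validation against a sequence catches reference mismatches", {
  seq <- protein_sequence("MKTV")
  good <- parse_hgvs_p(c("p.M1A", "p.V4G"))
  expect_identical(validate_against_sequence(good, seq), good)
  bad <- parse_hgvs_p("p.K3R")
  expect_error(validate_against_sequence(bad, seq),
               "reference mismatch at position 3")
  expect_error(validate_against_sequence(parse_hgvs_p("p.M9A"), seq),
               "outside")
})

test_that("the packaged topology map has the 25-region transporter architecture", {
  topo <- fixture_topo()
  seq <- fixture_seq()
  expect_equal(nrow(topo), 25L)
  counts <- table(topo$class)
  expect_equal(as.integer(counts[c("N-term", "TM", "EL", "IL", "C-term")]),
               c(1L, 12L, 6L, 5L, 1L))
  # contiguous closed intervals covering 1..L exactly
  expect_equal(sum(topo$end - topo$start + 1L), length(seq))
  expect_equal(topo$start[1], 1L)
  expect_equal(topo$end[nrow(topo)], length(seq))
})

test_that("region lookup agrees with an exhaustive interval scan", {
  topo <- fixture_topo()
  L <- topo$end[nrow(topo)]
  got <- region_of(seq_len(L), topo)
  # oracle: scan every region for every position
  for (pos in c(1L, sample(seq_len(L), 25), L)) {
    hits <- which(topo$start <= pos & topo$end >= pos)
    expect_length(hits, 1L)
    expect_equal(got$name[pos], topo$name[hits])
    expect_equal(got$class[pos], topo$class[hits])
  }
  expect_equal(got$name[1], "N-term")
  expect_equal(got$name[L], "C-term")
  expect_error(region_of(0L, topo), "outside")
  expect_error(region_of(L + 1L, topo), "outside")
})

test_that("topology validation rejects gaps, overlaps and unknown classes", {
  base <- data.frame(name = c("A", "B"), class = c("N-term", "C-term"),
                     start = c(1, 6), end = c(5, 10))
  expect_s3_class(topology_map(base), "topology_map")
  gap <- transform(base, start = c(1, 7))
  expect_error(topology_map(gap), "contiguous")
  overlap <- transform(base, start = c(1, 5))
  expect_error(topology_map(overlap), "contiguous")
  expect_error(topology_map(transform(base, class = c("N-term", "XX"))),
               "unknown region class")
  expect_error(topology_map(base, L = 11), "sequence length")
})

test_that("variant density counts variants per region residue", {
  topo <- topology_map(data.frame(
    name = c("N-term", "TM1", "C-term"), class = c("N-term", "TM", "C-term"),
    start = c(1, 5, 10), end = c(4, 9, 12)))
  v <- parse_hgvs_p(c("p.A5G", "p.A6G", "p.A6W", "p.A12G"))
  d <- region_density(v, topo)
  expect_equal(d$regions$n_variants, c(0L, 3L, 1L))
  expect_equal(d$regions$density, c(0, 3 / 5, 1 / 3))
  expect_equal(d$overall, 4 / 12)
  # invariant to row order
  d2 <- region_density(v[c(3, 1, 4, 2), ], topo)
  expect_equal(d2$regions, d$regions)
  # duplicates are a hard error, and the empty set gives all-zero densities
  expect_error(region_density(v[c(1, 1), ], topo), "duplicate")
  d0 <- region_density(v[0, ], topo)
  expect_true(all(d0$regions$density == 0))
  expect_equal(d0$overall, 0)
})
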