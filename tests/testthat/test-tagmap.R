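test_that("PST files round-trip and malformed input is rejected by line", {
  set.seed(21)
  psts <- pst_table(sprintf("s%03d", 1:100),
                    replicate(100, random_peptide(sample(3:5, 1))),
                    runif(100, 1, 900), runif(100, 19, 900))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_psts(psts, f)
  got <- read_psts(f)
  expect_identical(got$spectrum_id, psts$spectrum_id)
  expect_identical(got$tag, psts$tag)
  expect_equal(got$mn, psts$mn, tolerance = 1e-5)
  expect_equal(got$mc, psts$mc, tolerance = 1e-5)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# header", "s1\tAAA\t100.0\t200.0", "s2\tAAA\t100.0"), bad)
  expect_error(read_psts(bad), "line 3")
  badtag <- withr::local_tempfile(fileext = ".tsv")
  writeLines("s1\tAA\t100.0\t200.0", badtag)
  expect_error(read_psts(badtag), "length")
})

test_that("find_tag locates all (overlapping) occurrences, I/L-blind", {
  expect_identical(find_tag("FSQ", "RLFSQK"), 3L)
  expect_identical(find_tag("AIA", "KALAK"), 2L)
  expect_identical(find_tag("AIA", "KALAK", il_equivalent = FALSE), integer())
  expect_identical(find_tag("WWW", "KALAK"), integer())
  expect_identical(find_tag("AAA", "AAAAA"), 1:3)
})

test_that("flank verification recovers the tryptic peptide around a tag", {
  seg <- list(contig = "c", strand = "+", frame = 0, aa = "RLFSQKA",
              gstart = 1, gend = 21)
  fl <- flanks_for("LFSQK", tag_start = 2, tag_len = 3)
  pst <- pst_table("s1", "FSQ", fl["mn"], fl["mc"])
  v <- verify_flanks(seg, 3L, pst[1, ])
  expect_identical(v$peptide, "LFSQK")
  expect_identical(v$aa_start, 2L)
  expect_identical(v$n_mods, 0L)

  # perturbing one flank beyond tolerance kills the placement
  pst_off <- pst_table("s1", "FSQ", fl["mn"] + 0.6, fl["mc"])
  expect_identical(nrow(verify_flanks(seg, 3L, pst_off[1, ])), 0L)
  # ... but within tolerance keeps it
  pst_ok <- pst_table("s1", "FSQ", fl["mn"] + 0.4, fl["mc"] - 0.4)
  expect_identical(verify_flanks(seg, 3L, pst_ok[1, ])$peptide, "LFSQK")
})

test_that("a modified prefix is explained by an eligible modification", {
  # M in the prefix, N-flank offset by the oxidation delta
  seg <- list(contig = "c", strand = "+", frame = 0, aa = "KMAFSQK",
              gstart = 1, gend = 21)
  fl <- flanks_for("MAFSQK", tag_start = 3, tag_len = 3)
  pst <- pst_table("s1", "FSQ", fl["mn"] + 15.99491, fl["mc"])
  v <- verify_flanks(seg, 4L, pst[1, ])
  expect_identical(v$peptide, "MAFSQK")
  expect_identical(v$n_mods, 1L)
  # with max_mods = 0 the same PST fails
  v0 <- verify_flanks(seg, 4L, pst[1, ], map_params(max_mods = 0))
  expect_identical(nrow(v0), 0L)
  # an ineligible shift (no matching residue) fails
  pst_bad <- pst_table("s1", "FSQ", fl["mn"] + 57.02146, fl["mc"])
  seg_nc <- list(contig = "c", strand = "+", frame = 0, aa = "KAAFSQK",
                 gstart = 1, gend = 21)
  expect_identical(nrow(verify_flanks(seg_nc, 4L, pst_bad[1, ])), 0L)
})

test_that("tryptic boundaries constrain verification", {
  # peptide start must follow K/R or segment start
  seg <- list(contig = "c", strand = "+", frame = 0, aa = "ALFSQKA",
              gstart = 1, gend = 21)
  fl <- flanks_for("LFSQK", tag_start = 2, tag_len = 3)
  pst <- pst_table("s1", "FSQ", fl["mn"], fl["mc"])
  expect_identical(nrow(verify_flanks(seg, 3L, pst[1, ])), 0L)
  # segment start qualifies as a boundary
  seg2 <- list(contig = "c", strand = "+", frame = 0, aa = "LFSQKA",
               gstart = 1, gend = 18)
  expect_identical(verify_flanks(seg2, 2L, pst[1, ])$peptide, "LFSQK")
  # missed-cleavage cap: two internal K need missed_cleavages >= 2
  seg3 <- list(contig = "c", strand = "+", frame = 0, aa = "RAKAKAFSQK",
               gstart = 1, gend = 30)
  fl3 <- flanks_for("AKAKAFSQK", tag_start = 6, tag_len = 3)
  pst3 <- pst_table("s1", "FSQ", fl3["mn"], fl3["mc"])
  expect_identical(nrow(verify_flanks(seg3, 7L, pst3[1, ],
                                      map_params(missed_cleavages = 1))), 0L)
  expect_identical(
    verify_flanks(seg3, 7L, pst3[1, ],
                  map_params(missed_cleavages = 2))$peptide, "AKAKAFSQK")
})

test_that("map_psts equals the exhaustive enumeration oracle", {
  set.seed(22)
  for (rep in 1:4) {
    params <- map_params(max_mods = rep %% 2)
    case <- make_mapping_case(params = params)
    got <- map_psts(case$psts, case$segments, params)
    want <- oracle_map_psts(case$psts, case$segments, params)
    expect_identical(hit_key(got), hit_key(want))
    expect_gt(nrow(got), 0)
  }
})

test_that("emitted hits reproduce their PST flank masses (self-consistency)", {
  set.seed(23)
  case <- make_mapping_case()
  params <- map_params()
  hits <- map_psts(case$psts, case$segments, params)
  expect_gt(nrow(hits), 0)
  co <- params$constants
  for (i in seq_len(nrow(hits))) {
    pst <- case$psts[case$psts$spectrum_id == hits$spectrum_id[i], ]
    tagn <- chartr("I", "L", pst$tag)
    pepn <- chartr("I", "L", hits$peptide[i])
    t0 <- regexpr(tagn, pepn, fixed = TRUE)[1]
    expect_gte(t0, 1)
    fl <- flanks_for(hits$peptide[i], t0, nchar(pst$tag), co)
    max_delta <- 57.03
    expect_lte(abs(fl[["mn"]] - pst$mn),
               params$tolerance + hits$n_mods[i] * max_delta)
    expect_lte(abs(fl[["mc"]] - pst$mc),
               params$tolerance + hits$n_mods[i] * max_delta)
  }
})

test_that("mapping is monotone in tolerance and max_mods and I/L-blind", {
  set.seed(24)
  case <- make_mapping_case(n_true = 4, n_decoy = 4)
  base <- map_psts(case$psts, case$segments, map_params(tolerance = 0.2))
  wide <- map_psts(case$psts, case$segments, map_params(tolerance = 0.8))
  expect_true(all(hit_key(base) %in% hit_key(wide)))
  m0 <- map_psts(case$psts, case$segments, map_params(max_mods = 0))
  m1 <- map_psts(case$psts, case$segments, map_params(max_mods = 1))
  key_nm <- function(h) paste(h$spectrum_id, h$contig, h$strand, h$start,
                              h$end)
  expect_true(all(key_nm(m0) %in% key_nm(m1)))

  # replacing I by L in the genome leaves the hit set invariant
  segs_il <- case$segments
  segs_il$aa <- chartr("I", "L", segs_il$aa)
  hits_a <- map_psts(case$psts, case$segments, map_params())
  hits_b <- map_psts(case$psts, segs_il, map_params())
  expect_identical(key_nm(hits_a), key_nm(hits_b))
})

test_that("a PST whose tag occurs nowhere contributes no hits", {
  segments <- six_frame_translate(c(g = random_dna_string(300)))
  psts <- pst_table("s1", "WWWWW", 300, 300)
  expect_identical(nrow(map_psts(psts, segments)), 0L)
})

test_that("hits files round-trip", {
  set.seed(25)
  case <- make_mapping_case()
  hits <- map_psts(case$psts, case$segments)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, f)
  got <- read_hits(f)
  rownames(hits) <- NULL
  expect_identical(got, hits)
})
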