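# a one-gene annotation: mRNA spanning [1001, 4000], CDS [1001, 2000] and
# [3001, 4000], on the + strand of contig c1
local_annotation <- function(mrna = c(1001, 4000),
                             cds = list(c(1001, 2000), c(3001, 4000)),
                             strand = "+") {
  f <- withr::local_tempfile(fileext = ".gff3", .local_envir = parent.frame())
  rows <- c(
    gff3_feature("c1", "gene", mrna[1], mrna[2], strand, id = "g1"),
    gff3_feature("c1", "mRNA", mrna[1], mrna[2], strand, id = "g1.t1",
                 parent = "g1"),
    vapply(seq_along(cds), function(i) {
      gff3_feature("c1", "CDS", cds[[i]][1], cds[[i]][2], strand,
                   id = paste0("g1.t1.cds", i), parent = "g1.t1")
    }, ""))
  write_mini_gff3(f, rows)
  parse_gff3(f)
}

hitrow <- function(start, end, spectrum = "s1", peptide = "AAAK",
                   strand = "+", contig = "c1") {
  data.frame(spectrum_id = spectrum, tag = "AAA", contig = contig,
             strand = strand, frame = 0L, peptide = peptide,
             start = as.integer(start), end = as.integer(end), n_mods = 0L,
             stringsAsFactors = FALSE)
}

clusters_of <- function(hits) {
  cluster_hits(hits, cluster_params(maxdist = 100000, minhit = 1, minpep = 1))
}

test_that("GFF3 parsing extracts mRNA and CDS intervals with parents", {
  ann <- local_annotation()
  expect_identical(length(ann$mrna), 1L)
  expect_identical(ann$mrna$ID, "g1.t1")
  expect_identical(ann$mrna$gene, "g1")
  expect_identical(length(ann$cds), 2L)
  expect_identical(unique(ann$cds$parent), "g1.t1")
  expect_identical(BiocGenerics::start(ann$mrna), 1001L)

  # orphan CDS kept with a warning
  f <- withr::local_tempfile(fileext = ".gff3")
  write_mini_gff3(f, gff3_feature("c1", "CDS", 10, 30, "+", id = "x",
                                  parent = "ghost"))
  expect_warning(ann2 <- parse_gff3(f), "orphan")
  expect_identical(length(ann2$cds), 1L)
})

test_that("IN/OUT/CROSS categories follow mRNA containment", {
  ann <- local_annotation()
  cl <- data.frame(contig = "c1", strand = "+",
                   start = c(1200L, 9000L, 3800L),
                   end = c(3900L, 9400L, 4600L), stringsAsFactors = FALSE)
  expect_identical(categorize_clusters(cl, ann), c("IN", "OUT", "CROSS"))
  # strand matters unless ignored
  cl_rev <- data.frame(contig = "c1", strand = "-", start = 1200L,
                       end = 3900L, stringsAsFactors = FALSE)
  expect_identical(categorize_clusters(cl_rev, ann), "OUT")
  expect_identical(categorize_clusters(cl_rev, ann, ignore_strand = TRUE),
                   "IN")
})

test_that("an empty annotation makes every cluster OUT and UNANNOTATED", {
  f <- withr::local_tempfile(fileext = ".gff3")
  write_mini_gff3(f, character())
  ann <- parse_gff3(f)
  hits <- rbind(hitrow(100, 129), hitrow(200, 229, spectrum = "s2"))
  cl <- clusters_of(hits)
  q <- qualify_clusters(cl, hits, ann)
  expect_identical(q$category, "OUT")
  expect_identical(q$annotation_label, "UNANNOTATED")
  expect_identical(q$consistency_label, "CHECK")
})

test_that("typical spectra are those with all their hits in the cluster", {
  hits <- rbind(
    hitrow(100, 129, spectrum = "only_here"),
    hitrow(200, 229, spectrum = "shared"),
    hitrow(50000, 50029, spectrum = "shared"),
    hitrow(50100, 50129, spectrum = "elsewhere"))
  cl <- cluster_hits(hits, cluster_params(maxdist = 1000, minhit = 1,
                                          minpep = 1))
  expect_identical(nrow(cl), 2L)
  expect_identical(count_typical_spectra(cl$hit_rows[[1]], hits), 1L)
  expect_identical(count_typical_spectra(cl$hit_rows[[2]], hits), 1L)

  # brute-force cross-check on random assignments
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(4:15, 1)
    h <- do.call(rbind, lapply(seq_len(n), function(i) {
      hitrow(i * 1000, i * 1000 + 29,
             spectrum = sample(sprintf("sp%d", 1:5), 1))
    }))
    rows <- sort(sample(n, sample(seq_len(n), 1)))
    want <- sum(vapply(unique(h$spectrum_id[rows]), function(s) {
      all(which(h$spectrum_id == s) %in% rows)
    }, TRUE))
    expect_identical(count_typical_spectra(rows, h), want)
  }
})

test_that("label families follow the confidence and consistency rules", {
  ann <- local_annotation()
  # 3 hits inside CDS1, distinct peptides, distinct spectra -> typical >= 2
  hits <- rbind(
    hitrow(1101, 1130, spectrum = "sp1", peptide = "AAAK"),
    hitrow(1201, 1230, spectrum = "sp2", peptide = "CCCK"),
    hitrow(1301, 1330, spectrum = "sp3", peptide = "DDDK"))
  q <- qualify_clusters(clusters_of(hits), hits, ann)
  expect_identical(q$annotation_label, "ANNOTATED")
  expect_identical(q$confidence_label, "SURE")     # 3 typical, 3 peptides
  expect_identical(q$consistency_label, "OK")      # all hits CDS-included
  expect_identical(q$category, "IN")
  expect_identical(q$hit_in, 3L)
  expect_identical(q$cds_in, 3L)

  # 2 typical spectra but 2 peptides -> POSSIBLE
  hits2 <- rbind(
    hitrow(1101, 1130, spectrum = "sp1", peptide = "AAAK"),
    hitrow(1201, 1230, spectrum = "sp2", peptide = "CCCK"))
  q2 <- qualify_clusters(clusters_of(hits2), hits2, ann)
  expect_identical(q2$confidence_label, "POSSIBLE")

  # 1 typical spectrum -> DUBIOUS
  hits3 <- hitrow(1101, 1130, spectrum = "sp1")
  q3 <- qualify_clusters(clusters_of(hits3), hits3, ann)
  expect_identical(q3$confidence_label, "DUBIOUS")

  # one hit outside any CDS -> ANNOTATED (>=1 in) but CHECK; the straddling
  # peptide counts toward cds_cross
  hits4 <- rbind(
    hitrow(1101, 1130, spectrum = "sp1", peptide = "AAAK"),
    hitrow(1950, 2030, spectrum = "sp2", peptide = "CCCK"),
    hitrow(2101, 2130, spectrum = "sp3", peptide = "DDDK"))
  q4 <- qualify_clusters(clusters_of(hits4), hits4, ann)
  expect_identical(q4$annotation_label, "ANNOTATED")
  expect_identical(q4$consistency_label, "CHECK")
  expect_identical(q4$hit_in, 1L)
  expect_identical(q4$cds_in, 1L)
  expect_identical(q4$cds_cross, 1L)
})

test_that("label assignment is total and respects its invariants", {
  ann <- local_annotation()
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(1:8, 1)
    start <- sample.int(6000, n, replace = TRUE)
    h <- do.call(rbind, lapply(seq_len(n), function(i) {
      hitrow(start[i], start[i] + 29,
             spectrum = sample(sprintf("sp%d", 1:4), 1),
             peptide = sample(c("AAAK", "CCCK", "DDDK"), 1))
    }))
    q <- qualify_clusters(clusters_of(h), h, ann)
    expect_true(all(q$annotation_label %in% c("ANNOTATED", "UNANNOTATED")))
    expect_true(all(q$confidence_label %in% c("DUBIOUS", "POSSIBLE", "SURE")))
    expect_true(all(q$consistency_label %in% c("OK", "CHECK")))
    expect_true(all(q$category %in% c("IN", "OUT", "CROSS")))
    expect_true(all(q$hit_in <= q$tot_hit))
    expect_true(all(q$hit_in[q$annotation_label == "ANNOTATED"] >= 1))
    expect_true(all(q$consistency_label[q$annotation_label ==
                                          "UNANNOTATED"] == "CHECK"))
    expect_true(all((q$hit_in == q$tot_hit) ==
                      (q$consistency_label == "OK")))
  }
})

test_that("cluster GFF3 export round-trips intervals and attributes", {
  ann <- local_annotation()
  hits <- rbind(
    hitrow(1101, 1130, spectrum = "sp1", peptide = "AAAK"),
    hitrow(1201, 1230, spectrum = "sp2", peptide = "CCCK"),
    hitrow(1301, 1330, spectrum = "sp3", peptide = "DDDK"))
  q <- qualify_clusters(clusters_of(hits), hits, ann)
  f <- withr::local_tempfile(fileext = ".gff3")
  clusters_to_gff3(q, hits, f)
  gr <- rtracklayer::import(f, format = "gff3")
  match_f <- gr[gr$type == "match"]
  parts <- gr[gr$type == "match_part"]
  expect_identical(length(match_f), 1L)
  expect_identical(length(parts), 3L)
  expect_identical(BiocGenerics::start(match_f), q$start)
  expect_identical(BiocGenerics::end(match_f), q$end)
  expect_identical(match_f$category, "IN")
  expect_identical(match_f$confidence, "SURE")
  expect_identical(sort(BiocGenerics::start(parts)), hits$start)
  expect_identical(sort(parts$peptide), sort(hits$peptide))
  expect_true(all(vapply(parts$Parent, function(p) p == q$cluster_id, TRUE)))

  # empty cluster set -> valid header-only GFF3
  f2 <- withr::local_tempfile(fileext = ".gff3")
  clusters_to_gff3(q[0, ], hits, f2)
  expect_identical(readLines(f2)[1], "##gff-version 3")

  # qualification table writes one row per cluster
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_table(q, f3)
  expect_identical(length(readLines(f3)), 2L)
})
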