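# Annotation resource loading, gene overlap kinds, family-collapsed gene
# counting, predicted haploinsufficiency, dosage hits and population
# frequency lookup.

test_that("the toy bundle loads and validation catches broken bundles", {
  b <- shared_bundle()
  expect_s3_class(b, "resource_bundle")
  expect_gt(nrow(b$genes), 20)
  expect_equal(nrow(b$dosage), 4L)

  # missing table
  d2 <- file.path(tempdir(), "broken-bundle-1")
  dir.create(d2, showWarnings = FALSE)
  file.copy(list.files(shared_bundle_dir(), full.names = TRUE), d2,
            overwrite = TRUE)
  unlink(file.path(d2, "population_cnvs.tsv"))
  expect_error(load_resources(d2), "population_cnvs.tsv")

  # missing constraint column is named
  d3 <- file.path(tempdir(), "broken-bundle-2")
  dir.create(d3, showWarnings = FALSE)
  file.copy(list.files(shared_bundle_dir(), full.names = TRUE), d3,
            overwrite = TRUE)
  g <- readLines(file.path(d3, "genes.tsv"))
  g[2] <- sub("\tpLI\t", "\tnotpli\t", g[2])
  writeLines(g, file.path(d3, "genes.tsv"))
  expect_error(load_resources(d3), "pLI")

  # missing schema line
  d4 <- file.path(tempdir(), "broken-bundle-3")
  dir.create(d4, showWarnings = FALSE)
  file.copy(list.files(shared_bundle_dir(), full.names = TRUE), d4,
            overwrite = TRUE)
  writeLines(readLines(file.path(d4, "genes.tsv"))[-1],
             file.path(d4, "genes.tsv"))
  expect_error(load_resources(d4), "schema")

  # empty population table is a valid bundle with no frequency matches
  d5 <- file.path(tempdir(), "empty-pop-bundle")
  dir.create(d5, showWarnings = FALSE)
  file.copy(list.files(shared_bundle_dir(), full.names = TRUE), d5,
            overwrite = TRUE)
  writeLines(readLines(file.path(d5, "population_cnvs.tsv"))[1:2],
             file.path(d5, "population_cnvs.tsv"))
  b5 <- load_resources(d5)
  expect_equal(nrow(b5$popcnv), 0L)
  m <- max_population_frequency(b5, list(chrom = "1", start = 0L,
                                         end = 1000L, type = "DEL"))
  expect_true(is.na(m$frequency))
})

test_that("gene overlap kinds distinguish complete, internal and partial sides", {
  b <- shared_bundle()
  # HIGENE1 spans 1:1,000,000-1,016,500 on the + strand
  full <- overlapping_genes(b, list(chrom = "1", start = 995000L, end = 1025000L))
  expect_equal(full$overlap_kind[full$symbol == "HIGENE1"], "complete")
  intron <- overlapping_genes(b, list(chrom = "1", start = 1005000L, end = 1006000L))
  expect_equal(intron$overlap_kind[intron$symbol == "HIGENE1"], "internal")
  left <- overlapping_genes(b, list(chrom = "1", start = 990000L, end = 1004600L))
  expect_equal(left$overlap_kind[left$symbol == "HIGENE1"], "partial_5prime")
  right <- overlapping_genes(b, list(chrom = "1", start = 1012600L, end = 1030000L))
  expect_equal(right$overlap_kind[right$symbol == "HIGENE1"], "partial_3prime")
})

test_that("indexed gene overlap equals the linear-scan oracle on random probes", {
  b <- shared_bundle()
  set.seed(31)
  for (i in 1:100) {
    chrom <- sample(c("1", "2"), 1)
    s <- sample.int(9.5e6, 1)
    probe <- list(chrom = chrom, start = s, end = s + sample.int(500000, 1))
    got <- sort(overlapping_genes(b, probe)$symbol)
    expect_equal(got, sort(oracle_overlapping_symbols(b$genes, probe)))
  }
})

test_that("family collapsing counts a disease-free family as one unit", {
  b <- shared_bundle()
  # 3 FAMA genes, none disease-associated -> 1
  expect_equal(count_genes(b, list(chrom = "1", start = 3000000L,
                                   end = 3040000L)), 1L)
  # 3 FAMB genes, one disease-associated -> 3
  expect_equal(count_genes(b, list(chrom = "1", start = 3100000L,
                                   end = 3140000L)), 3L)
  # genes without families count individually
  expect_equal(count_genes(b, list(chrom = "1", start = 4000000L,
                                   end = 4250000L)), 3L)
  # count <= raw overlap count always
  set.seed(8)
  for (i in 1:50) {
    s <- sample.int(9e6, 1)
    probe <- list(chrom = sample(c("1", "2"), 1), start = s,
                  end = s + sample.int(1000000, 1))
    expect_lte(count_genes(b, probe), nrow(overlapping_genes(b, probe)))
  }
})

test_that("predicted HI honours the printed boundary directions", {
  g <- function(pLI, oe, hi) data.table::data.table(pLI = pLI, oe_upper = oe,
                                                    hi_index = hi)
  expect_true(predicted_hi(g(0.95, 0.2, 5)))
  expect_false(predicted_hi(g(0.95, 0.4, 5)))
  expect_true(predicted_hi(g(0.9, 0.34, 10)))   # inclusive pLI and HI, exclusive oe
  expect_false(predicted_hi(g(0.89, 0.34, 10)))
  expect_false(predicted_hi(g(0.9, 0.35, 10)))
  expect_false(predicted_hi(g(0.9, 0.34, 11)))
  expect_false(predicted_hi(g(NA, 0.2, 5)))

  # monotonicity: improving any metric never flips TRUE -> FALSE
  set.seed(12)
  for (i in 1:100) {
    pLI <- stats::runif(1); oe <- stats::runif(1, 0, 0.7); hi <- stats::runif(1, 0, 30)
    if (predicted_hi(g(pLI, oe, hi))) {
      expect_true(predicted_hi(g(min(1, pLI + stats::runif(1, 0, 0.1)),
                                 oe * stats::runif(1), hi * stats::runif(1))))
    }
  }
})

test_that("dosage hits are type-routed with element-covered fractions", {
  b <- shared_bundle()
  # DEL fully covering the HI gene
  h <- dosage_hits(b, list(chrom = "1", start = 995000L, end = 1025000L), "DEL")
  expect_equal(h$fraction[h$element == "HIGENE1"], 1.0)
  # DUP over an HI-only gene: no dosage hit
  h2 <- dosage_hits(b, list(chrom = "1", start = 995000L, end = 1025000L), "DUP")
  expect_equal(nrow(h2[h2$class == "gene"]), 0L)
  # DEL covering exactly half of the HI region (1:6,000,000-6,050,000)
  h3 <- dosage_hits(b, list(chrom = "1", start = 6000000L, end = 6025000L), "DEL")
  expect_equal(h3$fraction[h3$element == "HIREG1"], 0.5)
})

test_that("population frequency lookup returns the maximum qualifying match", {
  b <- shared_bundle()
  # identical match
  m <- max_population_frequency(b, list(chrom = "2", start = 2040000L,
                                        end = 2060000L, type = "DUP"))
  expect_equal(m$frequency, 0.05)
  expect_equal(m$source, "gnomAD_controls")
  # three qualifying entries: AF {0.02, 0.03, 0.0001} -> 0.03
  m2 <- max_population_frequency(b, list(chrom = "1", start = 7000000L,
                                         end = 7010000L, type = "DEL"))
  expect_equal(m2$frequency, 0.03)
  expect_equal(m2$source, "DECIPHER")
  # type mismatch -> none
  m3 <- max_population_frequency(b, list(chrom = "2", start = 2040000L,
                                         end = 2060000L, type = "DEL"))
  expect_true(is.na(m3$frequency))
})

test_that("re-loading the same bundle yields identical query answers", {
  b1 <- load_resources(shared_bundle_dir())
  b2 <- load_resources(shared_bundle_dir())
  probe <- list(chrom = "1", start = 3000000L, end = 4500000L)
  expect_identical(overlapping_genes(b1, probe), overlapping_genes(b2, probe))
  expect_identical(count_genes(b1, probe), count_genes(b2, probe))
})
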