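# Evidence assignment per section, the LoF decision tree, user evidence
# merging, classification bands, and the end-to-end golden interpretations.

cnv_of <- function(chrom, start, end, type) {
  list(chrom = chrom, start = start, end = end, type = type)
}

test_that("the shipped rubric validates and covers both arms", {
  r <- default_rubric()
  expect_s3_class(r, "rubric")
  for (id in names(r$criteria)) {
    cr <- r$criteria[[id]]
    expect_true(cr$default >= cr$min && cr$default <= cr$max, label = id)
  }
  expect_equal(r$criteria$L2A$default, 1.0)
  expect_equal(r$criteria$G2C$default, -1.0)
})

test_that("section 1 routes on genomic content", {
  b <- shared_bundle()
  r <- default_rubric()
  genes2 <- evaluate_section1(cnv_of("1", 2990000L, 3040000L, "DEL"), b, r)
  expect_equal(genes2$criterion, "L1A")
  intergenic <- evaluate_section1(cnv_of("1", 8000000L, 8050000L, "DEL"), b, r)
  expect_equal(intergenic$criterion, "L1B")
  # a dosage region with no gene still counts as important content
  region_only <- evaluate_section1(cnv_of("1", 6000000L, 6010000L, "DEL"), b, r)
  expect_equal(region_only$criterion, "L1A")
  # gain ids mirror the loss ids
  expect_equal(evaluate_section1(cnv_of("1", 8000000L, 8050000L, "DUP"),
                                 b, r)$criterion, "G1B")
})

test_that("loss section 2 assigns established, benign and predicted criteria", {
  b <- shared_bundle()
  r <- default_rubric()
  # complete overlap of an established HI gene
  s2 <- evaluate_section2_loss(cnv_of("1", 995000L, 1025000L, "DEL"), b, r)
  expect_equal(s2$criterion, "L2A")
  expect_equal(s2$points, 1.0)
  # contained in the benign loss region (2:3,000,000-3,100,000), only BLG1
  s2f <- evaluate_section2_loss(cnv_of("2", 3030000L, 3060000L, "DEL"), b, r)
  expect_equal(s2f$criterion, "L2F")
  expect_equal(s2f$points, -1.0)
  # overlapping the benign region plus a gene outside it
  s2g <- evaluate_section2_loss(cnv_of("2", 3030000L, 3120000L, "DEL"), b, r)
  expect_equal(s2g$criterion, "L2G")
  expect_equal(s2g$points, 0)
  # predicted-HI gene only (PHI corner gene with all three cut-offs met)
  phi <- b$genes[predicted_hi(b$genes) & grepl("^PHI", b$genes$symbol)][1]
  s2h <- evaluate_section2_loss(cnv_of("1", phi$start - 1000L,
                                       phi$end + 1000L, "DEL"), b, r)
  expect_equal(s2h$criterion, "L2H")
  expect_equal(s2h$points, 0.15)
  # ordinary gene, nothing established or predicted: no section-2 item
  none <- evaluate_section2_loss(cnv_of("1", 2000000L, 2010000L, "DEL"), b, r)
  expect_equal(nrow(none), 0L)
})

test_that("partial overlaps of an HI gene weight the 5' and 3' sides", {
  b <- shared_bundle()
  r <- default_rubric()
  # 5' partial with coding sequence involved -> 0.90
  s2c <- evaluate_section2_loss(cnv_of("1", 990000L, 1004600L, "DEL"), b, r)
  expect_equal(s2c$criterion, "L2C")
  expect_equal(s2c$points, 0.90)
  # 3' partial removing exons beyond the last one -> 0.90
  s2d <- evaluate_section2_loss(cnv_of("1", 1011000L, 1030000L, "DEL"), b, r)
  expect_equal(s2d$criterion, "L2D")
  expect_equal(s2d$points, 0.90)
  # 3' partial removing only the last exon, pathogenic variants known there
  # (LEGENE spans 1:5,000,000-5,012,500 with a last-exon pathogenic variant)
  s2d2 <- evaluate_section2_loss(cnv_of("1", 5011000L, 5020000L, "DEL"), b, r)
  expect_equal(s2d2$criterion, "L2D")
  expect_equal(s2d2$points, 0.90)
})

test_that("the LoF tree traces frameshift/NMD, in-frame and intron-only paths", {
  b <- shared_bundle()
  higene1 <- b$genes[b$genes$symbol == "HIGENE1"]
  # one 500 bp internal coding exon removed: frameshift, NMD-competent,
  # LoF-mechanism gene -> very strong
  vs <- assess_pvs1_loss(cnv_of("1", 1007900L, 1008600L, "DEL"), higene1, b)
  expect_equal(vs$strength, "very_strong")
  expect_true("nmd_competent" %in% vs$path)
  expect_true("lof_mechanism" %in% vs$path)

  # 99 bp exon of HIGENE2: in-frame, ~5% of the protein, no curated
  # variants -> moderate
  higene2 <- b$genes[b$genes$symbol == "HIGENE2"]
  mo <- assess_pvs1_loss(cnv_of("1", 1103900L, 1104200L, "DEL"), higene2, b)
  expect_equal(mo$strength, "moderate")
  expect_true("in_frame" %in% mo$path)

  # intron-only deletion: no LoF
  no <- assess_pvs1_loss(cnv_of("1", 1005000L, 1006000L, "DEL"), higene1, b)
  expect_equal(no$strength, "none")

  # intragenic deletion routes through L2E with the mapped points
  r <- default_rubric()
  s2e <- evaluate_section2_loss(cnv_of("1", 1007900L, 1008600L, "DEL"), b, r)
  expect_equal(s2e$criterion, "L2E")
  expect_equal(s2e$points, 0.90)
  s2e2 <- evaluate_section2_loss(cnv_of("1", 1103900L, 1104200L, "DEL"), b, r)
  expect_equal(s2e2$points, 0.30)
})

test_that("gain section 2 mirrors the loss arm with conservative intragenic calls", {
  b <- shared_bundle()
  r <- default_rubric()
  g2a <- evaluate_section2_gain(cnv_of("2", 995000L, 1025000L, "DUP"), b, r)
  expect_equal(g2a$criterion, "G2A")
  expect_equal(g2a$points, 1.0)
  g2c <- evaluate_section2_gain(cnv_of("2", 2040000L, 2060000L, "DUP"), b, r)
  expect_equal(g2c$criterion, "G2C")
  expect_equal(g2c$points, -1.0)
  # intragenic duplication: unknown orientation, 0 points
  g2i <- evaluate_section2_gain(cnv_of("2", 5001000L, 5002000L, "DUP"), b, r)
  expect_equal(g2i$criterion, "G2I")
  expect_equal(g2i$points, 0)
  expect_match(g2i$rationale, "unknown")
  # one breakpoint inside a disease gene
  g2l <- evaluate_section2_gain(cnv_of("2", 5005000L, 5030000L, "DUP"), b, r)
  expect_equal(g2l$criterion, "G2L")
  expect_equal(g2l$points, 0)
})

test_that("section 3 applies the loss and gain gene-count bands", {
  b <- shared_bundle()
  r <- default_rubric()
  # dense block on 2:6,000,000+ holds 60 single genes 20 kb apart
  span <- function(n) cnv_of("2", 6000000L, 6000000L + (n - 1L) * 20000L + 9000L, "DEL")
  expect_equal(evaluate_section3(span(10), b, r)$points, 0)
  expect_equal(evaluate_section3(span(25), b, r)$criterion, "L3B")
  expect_equal(evaluate_section3(span(25), b, r)$points, 0.45)
  expect_equal(evaluate_section3(span(35), b, r)$criterion, "L3C")
  expect_equal(evaluate_section3(span(35), b, r)$points, 0.90)
  gspan <- function(n) { x <- span(n); x$type <- "DUP"; x }
  expect_equal(evaluate_section3(gspan(34), b, r)$points, 0)
  expect_equal(evaluate_section3(gspan(35), b, r)$criterion, "G3B")
  expect_equal(evaluate_section3(gspan(50), b, r)$criterion, "G3C")
})

test_that("section 4 fires only on common population variation", {
  b <- shared_bundle()
  r <- default_rubric()
  common <- evaluate_section4_frequency(cnv_of("1", 7000000L, 7010000L, "DEL"),
                                        b, r)
  expect_equal(common$criterion, "L4O")
  expect_equal(common$points, -1.0)
  rare <- evaluate_section4_frequency(cnv_of("1", 2000000L, 2010000L, "DEL"),
                                      b, r)
  expect_equal(nrow(rare), 0L)
  nomatch <- evaluate_section4_frequency(cnv_of("1", 8000000L, 8050000L, "DEL"),
                                         b, r)
  expect_equal(nrow(nomatch), 0L)
})

test_that("user evidence unions, overrides and is range-checked", {
  r <- default_rubric()
  auto <- evaluate_section2_loss(
    cnv_of("1", 4099000L, 4110000L, "DEL"), shared_bundle(), r)
  expect_equal(auto$criterion, "L2H")
  merged <- merge_user_evidence(auto, list(list(criterion = "5A")), r)
  expect_true("5A" %in% merged$criterion)
  expect_equal(merged$points[merged$criterion == "5A"], 0.45)

  if (nrow(auto)) {
    over <- merge_user_evidence(auto, list(list(criterion = auto$criterion[1],
                                                points = 0)), r)
    expect_equal(over$points[over$criterion == auto$criterion[1]], 0)
    expect_match(over$rationale[over$criterion == auto$criterion[1]],
                 "overrides automatic")
  }
  expect_error(merge_user_evidence(auto, list(list(criterion = "5A",
                                                   points = 9)), r),
               "outside rubric range")
  expect_error(merge_user_evidence(auto, list(list(criterion = "NOPE")), r),
               "unknown rubric criterion")
})

test_that("classification bands map totals onto the five tiers", {
  r <- default_rubric()
  totals <- c(-1.0, -0.99, -0.98, -0.90, -0.89, 0, 0.89, 0.90, 0.98, 0.99, 1.0)
  want <- c("Benign", "Benign", "Likely benign", "Likely benign", "VUS",
            "VUS", "VUS", "Likely pathogenic", "Likely pathogenic",
            "Pathogenic", "Pathogenic")
  for (i in seq_along(totals)) {
    ev <- data.table::data.table(criterion = "user", points = totals[i],
                                 section = 4L, rationale = "", auto = FALSE)
    cls <- classify(ev, r)
    expect_equal(cls$category, want[i], label = sprintf("total %.2f", totals[i]))
    expect_equal(cls$category, oracle_band(totals[i]))
  }
  # totals built from sums of real point values classify consistently
  ev <- data.table::data.table(criterion = c("a", "b"), points = c(0.45, 0.45),
                               section = 2L, rationale = "", auto = TRUE)
  expect_equal(classify(ev, r)$category, "Likely pathogenic")
})

test_that("golden fixtures classify as hand-traced and deterministically", {
  b <- shared_bundle()
  toys <- toy_cnv_fixtures()
  for (i in seq_len(nrow(toys))) {
    cnv <- as.list(toys[i])
    res <- interpret(cnv, b)
    expect_equal(res$classification$total, toys$expected_total[i],
                 label = toys$name[i])
    expect_equal(res$classification$category, toys$expected_category[i],
                 label = toys$name[i])
    res2 <- interpret(cnv, b)
    expect_identical(res$report, res2$report)
  }
})

test_that("type routing and evidence-direction invariants hold", {
  b <- shared_bundle()
  toys <- toy_cnv_fixtures()
  for (i in seq_len(nrow(toys))) {
    cnv <- as.list(toys[i])
    res <- interpret(cnv, b)
    ids <- res$report$criterion[res$report$criterion != "TOTAL"]
    pre <- if (cnv$type == "DEL") "G" else "L"
    expect_false(any(startsWith(ids, pre)))
    # a positive user item never moves the class toward benign
    tiers <- c("Benign", "Likely benign", "VUS", "Likely pathogenic",
               "Pathogenic")
    res_up <- interpret(cnv, b, user_evidence = list(list(criterion = "5A")))
    expect_gte(match(res_up$classification$category, tiers),
               match(res$classification$category, tiers))
    # frequency evidence is never positive
    s4 <- res$report[res$report$criterion %in% c("L4O", "G4O")]
    if (nrow(s4)) expect_lte(max(s4$points), 0)
  }
})
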