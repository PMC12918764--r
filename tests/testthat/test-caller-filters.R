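# Caller-specific confidence rules: printed thresholds, boundary semantics,
# dispatch, and filter properties.

one_call <- function(type = "DEL", qual = NA, filter = "PASS", gt = "0/1",
                     ft = "PASS", ...) {
  cnv_calls(chrom = "1", start = 1000L, end = 2000L, type = type,
            caller = "x", qual = qual, filter = filter, genotype = gt,
            ft = ft, metrics = list(...))
}

test_that("CNVpytor rule fires on pytorP1, Q0 and the near-diploid RD band", {
  kept <- filter_cnvpytor(one_call(pytorP1 = 0.01, Q0 = 0.2, pytorRD = 0.4))
  expect_true(kept$kept)

  p1 <- filter_cnvpytor(one_call(pytorP1 = 0.06, Q0 = 0.2, pytorRD = 0.4))
  expect_false(p1$kept)
  expect_equal(p1$reasons, "pytorP1")

  rd <- filter_cnvpytor(one_call(pytorP1 = 0.01, Q0 = 0.2, pytorRD = 1.0))
  expect_false(rd$kept)
  expect_equal(rd$reasons, "pytorRD")

  # band edges are exclusive: RD exactly 0.75 or 1.25 is outside the band
  expect_true(filter_cnvpytor(one_call(pytorP1 = 0.01, Q0 = 0.2, pytorRD = 0.75))$kept)
  expect_true(filter_cnvpytor(one_call(pytorP1 = 0.01, Q0 = 0.2, pytorRD = 1.25))$kept)
  expect_false(filter_cnvpytor(one_call(pytorP1 = 0.01, Q0 = 0.95, pytorRD = 0.4))$kept)
})

test_that("ControlFREEC removes W or KS above 0.05, keeping the boundary", {
  expect_true(filter_controlfreec(one_call(W = 0.04, KS = 0.04))$kept)
  expect_false(filter_controlfreec(one_call(W = 0.06, KS = 0.01))$kept)
  expect_true(filter_controlfreec(one_call(W = 0.05, KS = 0.05))$kept)
})

test_that("delly/Manta PASS+genotype rule", {
  expect_true(filter_pass_gt(one_call(filter = "PASS", ft = "PASS", gt = "0/1"))$kept)
  expect_false(filter_pass_gt(one_call(filter = "LowQual", ft = "PASS", gt = "0/1"))$kept)
  expect_false(filter_pass_gt(one_call(filter = "PASS", ft = "PASS", gt = "0/0"))$kept)
  expect_false(filter_pass_gt(one_call(filter = "PASS", ft = "LowGQ", gt = "0/1"))$kept)
  # missing genotype treated as non-0/0
  expect_true(filter_pass_gt(one_call(filter = "PASS", ft = "PASS",
                                      gt = NA_character_))$kept)
})

test_that("lumpy QUAL threshold is a strict < 120", {
  expect_false(filter_lumpy(one_call(qual = 119))$kept)
  expect_true(filter_lumpy(one_call(qual = 120))$kept)
  expect_true(filter_lumpy(one_call(qual = 500))$kept)
})

test_that("Wham rule is type-aware over max_CW, TF and U", {
  expect_true(filter_wham(one_call("DEL", max_CW = 0.3, TF = 3))$kept)
  expect_false(filter_wham(one_call("DEL", max_CW = 0.3, TF = 2))$kept)
  expect_false(filter_wham(one_call("DUP", max_CW = 0.3, U = 1))$kept)
  expect_false(filter_wham(one_call("DEL", max_CW = 0.19, TF = 5))$kept)
})

test_that("GRIDSS removes any call labelled NO_ASSEMBLY", {
  expect_true(filter_gridss(one_call(filter = "PASS"))$kept)
  expect_false(filter_gridss(one_call(filter = "NO_ASSEMBLY"))$kept)
  expect_false(filter_gridss(one_call(filter = "NO_ASSEMBLY;PASS"))$kept)
})

test_that("ExomeDepth rule over BF and observed/expected read ratio", {
  expect_true(filter_exomedepth(one_call("DEL", BF = 20, reads_ratio = 0.5))$kept)
  expect_false(filter_exomedepth(one_call("DEL", BF = 20, reads_ratio = 0.9))$kept)
  expect_false(filter_exomedepth(one_call("DUP", BF = 14, reads_ratio = 1.5))$kept)
  expect_true(filter_exomedepth(one_call("DUP", BF = 15, reads_ratio = 1.1))$kept)
})

test_that("GATK4 piecewise thresholds evaluate and bound correctly", {
  expect_equal(gatk4_qs_threshold("DEL", 0, 70), 700)
  expect_false(filter_gatk4(one_call("DEL", QS = 699, CN = 0, nt = 70))$kept)
  expect_equal(gatk4_qs_threshold("DEL", 1, 5), 100)
  expect_true(filter_gatk4(one_call("DEL", QS = 100, CN = 1, nt = 5))$kept)
  expect_equal(gatk4_qs_threshold("DUP", 3, 200), 400)
  expect_false(filter_gatk4(one_call("DUP", QS = 399, CN = 3, nt = 200))$kept)
  # DEL outside CN {0,1} is outside the rule: kept with a warning
  expect_warning(out <- filter_gatk4(one_call("DEL", QS = 1, CN = 2, nt = 10)),
                 "CN outside")
  expect_true(out$kept)
  # bounds hold across the whole nt range
  nt <- 1:200
  expect_true(all(gatk4_qs_threshold("DEL", 0, nt) >= 100 &
                  gatk4_qs_threshold("DEL", 0, nt) <= 1000))
  expect_true(all(gatk4_qs_threshold("DEL", 1, nt) >= 100 &
                  gatk4_qs_threshold("DEL", 1, nt) <= 1000))
  expect_true(all(gatk4_qs_threshold("DUP", 3, nt) >= 50 &
                  gatk4_qs_threshold("DUP", 3, nt) <= 400))
})

test_that("filters are monotone in their quality metric", {
  set.seed(5)
  for (i in 1:50) {
    q <- stats::runif(1, 0, 300)
    lo <- filter_lumpy(one_call(qual = q))$kept
    hi <- filter_lumpy(one_call(qual = q + stats::runif(1, 0, 300)))$kept
    expect_true(!lo || hi)  # raising QUAL never flips kept -> removed
    bf <- stats::runif(1, 0, 40)
    lo2 <- filter_exomedepth(one_call("DEL", BF = bf, reads_ratio = 0.5))$kept
    hi2 <- filter_exomedepth(one_call("DEL", BF = bf + 10, reads_ratio = 0.5))$kept
    expect_true(!lo2 || hi2)
  }
})

test_that("dispatch keeps unruled callers, rejects unknown ones, reports removals", {
  # lumpy: removed iff QUAL < 120
  calls <- cnv_calls(chrom = "1", start = c(1000L, 5000L, 9000L),
                     end = c(2000L, 6000L, 10000L), type = "DEL",
                     caller = "lumpy", qual = c(100, 130, 119))
  res <- apply_caller_filters(calls)
  expect_equal(nrow(res$kept), 1L)
  expect_equal(res$kept$qual, 130)
  expect_equal(sum(res$report$removed), 2L)

  # cn.mops has no published rule: pass-through
  cm <- cnv_calls(chrom = "1", start = seq(1000L, 31000L, by = 10000L),
                  end = seq(2000L, 32000L, by = 10000L), type = "DUP",
                  caller = "cn.mops")
  expect_equal(nrow(apply_caller_filters(cm)$kept), 4L)

  bad <- cnv_calls(chrom = "1", start = 1000L, end = 2000L, type = "DEL",
                   caller = "nocaller")
  expect_error(apply_caller_filters(bad), "registered callers")
})

test_that("generated fixture outcomes match the per-record oracle table exactly", {
  fx <- shared_caller_fixture()
  for (cl in unique(fx$expected$caller)) {
    calls <- read_cnv_vcf(file.path(fx$dir, paste0(cl, ".vcf")), cl)
    res <- suppressWarnings(apply_caller_filters(calls))
    e <- fx$expected[fx$expected$caller == cl]
    expect_equal(res$outcome$kept, e$kept, info = cl)
    # removal reasons partition the removed set; survivors <= inputs
    expect_true(all(nzchar(res$outcome$reasons[!res$outcome$kept])))
    expect_true(all(res$outcome$reasons[res$outcome$kept] == ""))
    expect_lte(nrow(res$kept), nrow(calls))
  }
})
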