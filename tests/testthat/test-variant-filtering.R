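# helper: a variant record with nominal (clearly passing) annotations
nominal_variants <- function(n, chrom = "Chr1") {
  v <- data.frame(chrom = rep(chrom, n), pos = seq_len(n) * 1000,
                  ref = rep("A", n), alt = rep("T", n),
                  source_parent = rep("parent2", n),
                  QD = rep(25, n), FS = rep(5, n), MQ = rep(60, n),
                  MQRankSum = rep(0, n), ReadPosRankSum = rep(0, n),
                  truth_component = rep("inlier", n),
                  filter_status = rep("pass", n))
  class(v) <- c("parental_variants", "data.frame")
  v
}

test_that("soft filter applies the hard-filter expression with strict bounds", {
  v <- nominal_variants(6)
  v$QD[1] <- 4.9                      # fails QD < 5.0
  v$FS[2] <- 60.0                     # boundary: passes (strict)
  v$MQ[3] <- 50.0                     # boundary: passes
  v$MQRankSum[4] <- -12.5             # boundary: passes
  v$ReadPosRankSum[5] <- -8.0         # boundary: passes
  out <- apply_soft_filter(v)
  expect_equal(out$filter_status,
               c("soft_fail", rep("pass", 5)))

  # boundary record failing nothing
  vb <- nominal_variants(1)
  vb$QD <- 5.0; vb$FS <- 60.0; vb$MQ <- 50.0
  vb$MQRankSum <- -12.5; vb$ReadPosRankSum <- -8.0
  expect_equal(apply_soft_filter(vb)$filter_status, "pass")

  # missing annotations never trigger their clause
  vm <- nominal_variants(1)
  vm$QD <- NA; vm$MQRankSum <- NA
  expect_equal(apply_soft_filter(vm)$filter_status, "pass")
})

test_that("planted soft-filter violations are all flagged (brute force)", {
  set.seed(101)
  v <- nominal_variants(100)
  bad <- sample(100, 7)
  clauses <- list(function(r) { r$QD <- 3; r },
                  function(r) { r$FS <- 80; r },
                  function(r) { r$MQ <- 40; r },
                  function(r) { r$MQRankSum <- -15; r },
                  function(r) { r$ReadPosRankSum <- -9; r })
  for (i in seq_along(bad)) {
    f <- clauses[[(i %% 5) + 1]]
    v[bad[i], ] <- f(v[bad[i], ])
  }
  out <- apply_soft_filter(v)
  # brute-force clause evaluation as the oracle
  oracle <- with(v, QD < 5 | FS > 60 | MQ < 50 | MQRankSum < -12.5 |
                   ReadPosRankSum < -8)
  expect_equal(out$filter_status == "soft_fail", oracle)
  expect_equal(sum(out$filter_status == "soft_fail"), 7)
})

test_that("fit_dominant_gaussian recovers components and handles degeneracy", {
  # zero-variance input: SD floor, everything retained
  expect_warning(f0 <- fit_dominant_gaussian(rep(20, 50), 2, k_sd = 2.5),
                 "floor")
  expect_equal(f0$interval, c(20, 20), tolerance = 1e-4)

  # mixture recovery: 0.8 N(25,3) + 0.2 N(3,1)
  set.seed(102)
  x <- c(rnorm(8000, 25, 3), rnorm(2000, 3, 1))
  f2 <- fit_dominant_gaussian(x, 2, k_sd = 2.5)
  expect_lt(abs(f2$means[f2$dominant] - 25), 0.5)
  expect_equal(f2$interval, c(17.5, 32.5), tolerance = 0.5)
  expect_equal(sum(f2$weights), 1, tolerance = 1e-9)
  expect_equal(which.max(f2$weights), f2$dominant)

  # cross-check against an independently fitted mixture (mclust)
  if (requireNamespace("mclust", quietly = TRUE)) {
    suppressMessages(library(mclust))
    mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    dom <- which.max(mc$parameters$pro)
    expect_lt(abs(f2$means[f2$dominant] - mc$parameters$mean[dom]), 0.3)
    expect_lt(abs(f2$sds[f2$dominant] -
                    sqrt(mc$parameters$variance$sigmasq[dom])), 0.3)
  }

  # unimodal: retained fraction ~ P(|Z| <= 4)
  set.seed(103)
  xu <- rnorm(200000, 0, 10)
  fu <- fit_dominant_gaussian(xu, 1, k_sd = 4)
  frac <- mean(xu >= fu$interval[1] & xu <= fu$interval[2])
  expect_equal(frac, 2 * pnorm(4) - 1, tolerance = 5e-4)

  expect_error(fit_dominant_gaussian(1:5), "at least 10")
})

test_that("corrected filter removes region, MQ and Gaussian-tail failures", {
  set.seed(104)
  v <- nominal_variants(2000)
  v$QD <- rnorm(2000, 25, 3)
  v$FS <- abs(rnorm(2000, 0, 5))
  v$MQRankSum <- rnorm(2000, 0, 1)
  # variant inside a centromere interval fails regardless of annotations
  bed <- data.frame(chrom = "Chr1", start = 999, end = 2000,
                    class = "centromere")
  v$MQ[5] <- 49.9
  out <- corrected_filter(v, exclusion_bed = bed)
  expect_equal(out$filter_status[1], "region_fail")    # pos 1000 in [999,2000)
  expect_equal(out$filter_status[2], "region_fail")
  expect_equal(out$filter_status[3], "pass")           # pos 3000 outside
  expect_equal(out$filter_status[5], "corrected_fail") # MQ 49.9 < 50
  expect_s3_class(attr(out, "fits")$QD, "gaussian_fit")

  # empty input warns
  expect_warning(corrected_filter(nominal_variants(0)), "empty")
})

test_that("corrected filter separates a planted QD outlier mode", {
  set.seed(105)
  n <- 10000
  v <- nominal_variants(n)
  is_out <- seq_len(n) <= 2000
  v$QD[is_out] <- rnorm(2000, 3, 1)
  v$QD[!is_out] <- rnorm(8000, 25, 3)
  v$truth_component <- ifelse(is_out, "outlier", "inlier")
  # FS/MQRankSum held at nominal constants so removal is QD-driven
  out <- suppressWarnings(corrected_filter(v))
  removed <- out$filter_status == "corrected_fail"
  expect_gte(mean(removed[is_out]), 0.95)     # >= 95% of outliers removed
  expect_lte(mean(removed[!is_out]), 0.02)    # <= 2% of inliers lost
})

test_that("filter stages are idempotent and every removal is attributable", {
  set.seed(106)
  g <- tiny_genome()
  v <- simulate_parents(g, 5000, outlier_fraction = 0.2, seed = 107)
  bed <- data.frame(chrom = "Chr1", start = 10e6, end = 12e6, class = "TE")
  out <- filter_variants(v, exclusion_bed = bed)
  audit <- attr(out, "audit")
  expect_equal(sum(audit$n), nrow(v))
  expect_equal(sum(out$filter_status != "pass"),
               nrow(v) - sum(out$filter_status == "pass"))
  # re-running the full filter on the retained output with the stored
  # decision rule (fitted intervals) changes nothing
  kept <- out[out$filter_status == "pass", ]
  again <- filter_variants(kept, exclusion_bed = bed,
                           fits = attr(out, "fits"))
  expect_true(all(again$filter_status == "pass"))
})

test_that("biallelic selection picks the ALT parent by variant count", {
  mk <- function(n, chrom = "Chr1") {
    v <- nominal_variants(n, chrom)
    v$filter_status <- "pass"
    v
  }
  p1 <- mk(80); p2 <- mk(120)
  out <- select_biallelic_and_alt_parent(p1, p2)
  expect_equal(attr(out, "alt_parent"), "parent2")
  expect_equal(nrow(out), 120)

  # tie broken to parent1, with a message
  expect_message(tie <- select_biallelic_and_alt_parent(mk(50), mk(50)),
                 "parent1")
  expect_equal(attr(tie, "alt_parent"), "parent1")

  # indels and multiallelic records are excluded with reason
  p3 <- mk(100)
  p3$alt[1:2] <- "AT"          # indels
  p3$ref[3] <- "GG"
  p3$alt[4:5] <- "A,T"         # multiallelic
  out3 <- select_biallelic_and_alt_parent(p3, mk(10))
  expect_equal(sum(out3$filter_status == "non_biallelic"), 5)
  expect_equal(sum(out3$filter_status == "pass"), 95)
})

test_that("VCF and BED round-trips preserve variants and regions", {
  g <- tiny_genome()
  v <- simulate_parents(g, 50, outlier_fraction = 0.1, seed = 108)
  vcf <- tempfile(fileext = ".vcf.gz")
  write_parent_vcf(v, vcf, genome = g)
  back <- read_parent_vcf(vcf, source_parent = "parent2")
  expect_equal(back$chrom, v$chrom)
  expect_equal(back$pos, v$pos)
  expect_equal(back$ref, v$ref)
  expect_equal(back$QD, v$QD, tolerance = 1e-4)
  expect_equal(back$MQRankSum, v$MQRankSum, tolerance = 1e-4)

  bedf <- tempfile(fileext = ".bed")
  regions <- data.frame(chrom = c("Chr1", "Chr1"), start = c(0, 5e6),
                        end = c(1e5, 7e6), class = c("telomere", "centromere"))
  write_exclusion_bed(regions, bedf)
  rback <- read_exclusion_bed(bedf)
  expect_equal(rback$start, regions$start)
  expect_equal(rback$end, regions$end)
  expect_equal(rback$class, regions$class)
})
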