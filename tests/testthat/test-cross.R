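# build a genotype_paths-like object from explicit per-sample states over
# shared sites, with unit posteriors, for partition-arithmetic tests
paths_from_states <- function(states, pos, genome, ids = NULL) {
  states <- rbind(states)
  n <- nrow(states)
  if (is.null(ids)) ids <- sprintf("I%d", seq_len(n))
  onehot <- function(k) (states == k) * 1
  structure(list(sites = data.frame(chrom = "Chr1", pos = pos),
                 sample_ids = ids, states = states,
                 post = list(AA = onehot(1), AB = onehot(2), BB = onehot(3)),
                 loglik_fwd = rep(0, n), loglik_bwd = rep(0, n),
                 genome = genome, error_rate = 0.01),
            class = "genotype_paths")
}

test_that("build_markers partitions chromosomes at crossover breakpoints", {
  g <- tiny_genome(30)
  pos <- seq(0.5e6, 29.5e6, by = 0.5e6)
  # individual 1 switches AA->AB at 10 Mb; individual 2 AB->BB at 20 Mb
  s1 <- ifelse(pos < 10e6, 1L, 2L)
  s2 <- ifelse(pos < 20e6, 2L, 3L)
  paths <- paths_from_states(rbind(s1, s2), pos, g)
  cr <- build_markers(paths)
  expect_equal(nrow(cr$markers), 3)
  # breakpoints at the midpoints of the bracketing site intervals
  expect_equal(cr$markers$pos_bp,
               c(9.75e6 / 2, (9.75e6 + 19.75e6) / 2, (19.75e6 + 30e6) / 2))
  expect_equal(unname(cr$geno[1, ]), c(1L, 2L, 2L))
  expect_equal(unname(cr$geno[2, ]), c(2L, 2L, 3L))

  # homogeneous individual: same genotype at every marker
  s3 <- rep(1L, length(pos))
  cr3 <- build_markers(paths_from_states(rbind(s3, s2), pos, g))
  expect_true(all(cr3$geno[1, ] == 1L))

  # zero crossovers anywhere: single marker per chromosome, warning
  expect_warning(cr0 <- build_markers(paths_from_states(rbind(s3, s3), pos, g)),
                 "no crossovers")
  expect_equal(nrow(cr0$markers), 1)
})

test_that("marker genotypes match truth in a simulated population", {
  g <- default_genome(with_exclusions = FALSE)
  truth <- simulate_f2(g, 6, seed = 301)
  pv <- simulate_parents(g, 70000, outlier_fraction = 0, seed = 302)
  ac <- simulate_allele_counts(truth, pv, 0.2, error_rate = 0.01, seed = 303)
  paths <- reconstruct(ac, g)
  cr <- build_markers(paths)
  gtruth <- true_genotypes(truth, data.frame(chrom = cr$markers$chrom,
                                             pos = cr$markers$pos_bp))
  called <- !is.na(cr$geno)
  err <- mean(cr$geno[called] != gtruth[called])
  expect_lte(err, 0.01)
})

test_that("individual QC removes few-marker, duplicate and high-CO individuals", {
  set.seed(304)
  g <- default_genome(with_exclusions = FALSE)
  n <- 30
  truth <- simulate_f2(g, n, seed = 304)
  markers <- do.call(rbind, lapply(seq_len(nrow(g$chromosomes)), function(i)
    data.frame(chrom = g$chromosomes$chrom[i],
               pos_bp = seq(5e5, g$chromosomes$length_bp[i] - 5e5, by = 1e6))))
  geno <- true_genotypes(truth, data.frame(chrom = markers$chrom,
                                           pos = markers$pos_bp))
  rownames(geno) <- sprintf("I%02d", 1:n)
  m <- ncol(geno)
  # I01: almost all missing
  geno[1, seq_len(m - 8)] <- NA
  # I02 becomes a near-duplicate of I03: ~92% identity, differences in one
  # contiguous block (so only two extra apparent crossovers)
  geno[2, ] <- geno[3, ]
  blk <- 1:round(0.08 * m)
  geno[2, blk] <- ifelse(geno[2, blk] == 2L, 1L,
                         ifelse(geno[2, blk] == 1L, 2L, 2L))
  # I04: alternating genotypes on Chr1 -> far more than 25 crossovers
  chr1 <- which(markers$chrom == "Chr1")
  geno[4, chr1] <- rep(c(1L, 2L), length.out = length(chr1))
  cr <- make_cross(geno, markers, g)
  out <- qc_individuals(cr)
  gone <- setdiff(rownames(geno), rownames(out$geno))
  expect_true("I01" %in% gone)
  expect_true("I04" %in% gone)
  expect_true(xor("I02" %in% gone, "I03" %in% gone))
  # unrelated individuals (expected identity ~ 37.5%) are untouched
  expect_equal(nrow(out$geno), n - 3)
  expect_setequal(unique(out$qc_log$stage),
                  c("low_marker_count", "similar_genotype", "excess_crossovers"))

  # exact duplicate: exactly one of the pair goes
  geno2 <- geno[5:10, ]
  geno2[2, ] <- geno2[1, ]
  cr2 <- make_cross(geno2, markers, g)
  out2 <- qc_individuals(cr2, max_crossovers = 1e6)
  expect_equal(nrow(out2$geno), 5)
})

test_that("marker QC enforces missingness and segregation distortion", {
  dt <- distortion_test(100, 20, 0)
  expect_equal(dt$chisq, 220.0)
  expect_lt(dt$p, 1e-7)
  dt2 <- distortion_test(30, 60, 30)
  expect_equal(dt2$chisq, 0)
  expect_equal(dt2$p, 1)

  set.seed(305)
  n <- 150
  geno <- matrix(sample(1:3, n * 4, replace = TRUE, prob = c(1, 2, 1) / 4),
                 n, 4)
  # marker 2: 60% missing; marker 3: grossly distorted
  geno[sample(n, 90), 2] <- NA
  geno[, 3] <- sample(1:3, n, replace = TRUE, prob = c(0.85, 0.15, 0))
  cr <- make_cross(geno, data.frame(chrom = "Chr1", pos_bp = 1:4 * 1e6),
                   tiny_genome(30))
  out <- qc_markers(cr, max_missing_frac = 0.1, distortion_p = 1e-7)
  expect_equal(ncol(out$geno), 2)
  expect_setequal(out$qc_log$stage,
                  c("marker_missing", "segregation_distortion"))
  # QC log reconciles input and output sizes
  expect_equal(ncol(cr$geno) - ncol(out$geno), nrow(out$qc_log))
})

test_that("genetic map estimation recovers simulated distances", {
  # no recombinants: distance 0
  g1 <- matrix(c(1L, 2L, 3L, 1L, 2L, 3L), 3, 2)
  cr <- make_cross(g1, data.frame(chrom = "Chr1", pos_bp = c(1e6, 2e6)),
                   tiny_genome(30))
  cr <- estimate_genetic_map(cr)
  expect_equal(cr$markers$cm, c(0, 0))

  # 10 cM gap, n = 500: estimate within 10 +- 2 cM
  g <- tiny_genome(5, cm_per_mb = 2)    # 10 cM chromosome
  truth <- simulate_f2(g, 500, seed = 306)
  gtr <- true_genotypes(truth, data.frame(chrom = "Chr1", pos = c(1, 5e6)))
  cr2 <- make_cross(gtr, data.frame(chrom = "Chr1", pos_bp = c(1, 5e6)), g)
  cr2 <- estimate_genetic_map(cr2)
  expect_lt(abs(cr2$markers$cm[2] - 10), 2)

  # unsorted physical positions are rejected
  expect_error(make_cross(g1, data.frame(chrom = "Chr1",
                                         pos_bp = c(2e6, 1e6)),
                          tiny_genome(30)), "sorted")
})

test_that("cross csvr files round-trip losslessly", {
  set.seed(307)
  n <- 12; m <- 6
  geno <- matrix(sample(c(1:3, NA), n * m, replace = TRUE), n, m)
  markers <- data.frame(chrom = rep(c("Chr1", "Chr2"), each = 3),
                        pos_bp = rep(c(2e6, 8e6, 14e6), 2))
  cr <- make_cross(geno, markers,
                   pheno = data.frame(id = sprintf("ind_%04d", 1:n),
                                      DTF = round(rnorm(n, 30, 4), 3),
                                      RLN = round(rnorm(n, 12, 2), 3)))
  cr <- estimate_genetic_map(cr)
  path <- tempfile(fileext = ".csv")
  write_cross(cr, path)
  # file has n_markers + n_phenotypes rows
  expect_equal(length(readLines(path)), m + 2)
  back <- read_cross(path)
  expect_equal(unname(back$geno), unname(cr$geno))
  expect_equal(back$markers$chrom, cr$markers$chrom)
  expect_equal(back$markers$cm, cr$markers$cm, tolerance = 1e-6)
  expect_equal(back$markers$pos_bp, cr$markers$pos_bp)
  expect_equal(back$pheno$DTF, cr$pheno$DTF)
  expect_equal(back$pheno$RLN, cr$pheno$RLN)

  # a cross without phenotypes is rejected
  cr_nop <- make_cross(geno, markers)
  cr_nop <- estimate_genetic_map(cr_nop)
  expect_error(write_cross(cr_nop, tempfile()), "phenotype")
})
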