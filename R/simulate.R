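#' Default variant-quality annotation model
#'
#' Two-component model for the per-variant quality annotations written by
#' joint variant callers. Inlier variants follow the well-behaved component;
#' outliers (mismapped or artifactual calls) follow a displaced component
#' that the automated corrected filter is designed to remove. QD inliers are
#' N(25, 3) against an outlier mode at N(3, 1); FS is half-normal (strand
#' bias is non-negative); MQ is a point mass at 60 for inliers; the two
#' rank-sum annotations are near-zero for inliers and negatively displaced
#' for outliers.
#'
#' @return A list with one element per annotation, each holding `inlier` and
#'   `outlier` sampling functions of `n`.
#' @export
default_annotation_model <- function() {
  list(
    QD = list(inlier = function(n) stats::rnorm(n, 25, 3),
              outlier = function(n) stats::rnorm(n, 3, 1)),
    FS = list(inlier = function(n) abs(stats::rnorm(n, 0, 8)),
              outlier = function(n) abs(stats::rnorm(n, 0, 40)) + 20),
    MQ = list(inlier = function(n) rep(60, n),
              outlier = function(n) stats::rnorm(n, 42, 4)),
    MQRankSum = list(inlier = function(n) stats::rnorm(n, 0, 1),
                     outlier = function(n) stats::rnorm(n, -7, 2)),
    ReadPosRankSum = list(inlier = function(n) stats::rnorm(n, 0, 1),
                          outlier = function(n) stats::rnorm(n, -4, 2))
  )
}

#' Simulate parental SNP markers with quality annotations
#'
#' Draws biallelic SNP positions uniformly along the genome (unique, sorted
#' per chromosome) and attaches QD, FS, MQ, MQRankSum and ReadPosRankSum
#' annotations from a two-component inlier/outlier model. The generating
#' component of every variant is recorded so that filter performance can be
#' scored against truth.
#'
#' @param genome a `genome_spec`.
#' @param n_variants number of variants (>= 1).
#' @param annotation_model list as returned by [default_annotation_model()].
#' @param outlier_fraction proportion of variants drawn from the outlier
#'   component, in `[0, 1)`.
#' @param source_parent label recorded as the ALT-allele source parent.
#' @param seed integer seed.
#' @return A `parental_variants` data.frame with columns `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `source_parent`, the five annotations,
#'   `truth_component` (`"inlier"`/`"outlier"`) and `filter_status`
#'   (initialised to `"pass"`).
#' @export
simulate_parents <- function(genome, n_variants,
                             annotation_model = default_annotation_model(),
                             outlier_fraction = 0.2,
                             source_parent = "parent2", seed = NULL) {
  stopifnot(inherits(genome, "genome_spec"))
  if (n_variants < 1) stop("n_variants must be >= 1")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("outlier_fraction must be in [0, 1)")
  if (sum(genome$chromosomes$length_bp) <= 0) stop("zero-length genome")
  if (!is.null(seed)) set.seed(seed)

  lens <- genome$chromosomes$length_bp
  n_per <- as.vector(stats::rmultinom(1, n_variants, lens / sum(lens)))
  recs <- lapply(seq_along(lens), function(i) {
    if (n_per[i] == 0) return(NULL)
    pos <- sort(sample.int(lens[i], min(n_per[i], lens[i])))
    data.frame(chrom = genome$chromosomes$chrom[i], pos = pos)
  })
  out <- do.call(rbind, recs)
  n <- nrow(out)
  bases <- c("A", "C", "G", "T")
  out$ref <- sample(bases, n, replace = TRUE)
  out$alt <- vapply(out$ref, function(b) sample(setdiff(bases, b), 1), "")
  out$source_parent <- source_parent
  is_out <- stats::runif(n) < outlier_fraction
  for (ann in names(annotation_model)) {
    v <- numeric(n)
    if (any(!is_out)) v[!is_out] <- annotation_model[[ann]]$inlier(sum(!is_out))
    if (any(is_out)) v[is_out] <- annotation_model[[ann]]$outlier(sum(is_out))
    out[[ann]] <- v
  }
  out$truth_component <- ifelse(is_out, "outlier", "inlier")
  out$filter_status <- "pass"
  rownames(out) <- NULL
  class(out) <- c("parental_variants", "data.frame")
  out
}

# sample one gamete for one chromosome: crossover count ~ Poisson(length in
# Morgans), breakpoints uniform in bp (constant cM/Mb), starting phase random.
# Returns list(breaks = bp positions, start_allele = 0 or 1).
.sim_gamete <- function(length_bp, cm_per_mb) {
  morgans <- length_bp / 1e6 * cm_per_mb / 100
  n_co <- stats::rpois(1, morgans)
  list(breaks = sort(stats::runif(n_co, 0, length_bp)),
       start_allele = sample(0:1, 1))
}

# allele (0/1) of a gamete over the partition induced by `cuts` (sorted bp,
# excluding 0 and L): allele flips at each of the gamete's own breakpoints.
.gamete_alleles <- function(gam, cuts) {
  # for each interval between consecutive cuts, count gamete breaks before it
  n_breaks_before <- findInterval(cuts, gam$breaks)
  (gam$start_allele + n_breaks_before) %% 2
}

#' Simulate F2 individuals by biparental meiosis
#'
#' Each individual is the fusion of two independent gametes of the selfed F1.
#' Crossovers per gamete per chromosome are Poisson with mean equal to the
#' chromosome's genetic length in Morgans (Haldane model, no interference),
#' placed uniformly in physical coordinates (constant cM/Mb). Genotype state
#' frequencies converge to the Mendelian 1:2:1 as the population grows.
#'
#' @param genome a `genome_spec`.
#' @param n_individuals number of F2 plants (>= 1).
#' @param seed integer seed.
#' @return An `f2_truth` object: a list of individuals, each with `id`,
#'   `segments` (data.frame `chrom`, `start`, `end`, `state` in
#'   `AA`/`AB`/`BB`, tiling each chromosome) and `crossovers`
#'   (data.frame `chrom`, `pos`).
#' @export
simulate_f2 <- function(genome, n_individuals, seed = NULL) {
  stopifnot(inherits(genome, "genome_spec"))
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  states <- c("AA", "AB", "BB")

  one_individual <- function(idx) {
    segs <- vector("list", nrow(genome$chromosomes))
    cos <- vector("list", nrow(genome$chromosomes))
    for (i in seq_len(nrow(genome$chromosomes))) {
      L <- genome$chromosomes$length_bp[i]
      chrom <- genome$chromosomes$chrom[i]
      g1 <- .sim_gamete(L, genome$cm_per_mb)
      g2 <- .sim_gamete(L, genome$cm_per_mb)
      bp <- sort(unique(c(g1$breaks, g2$breaks)))
      starts <- c(0, bp)
      a1 <- .gamete_alleles(g1, starts)
      a2 <- .gamete_alleles(g2, starts)
      state <- states[a1 + a2 + 1]
      # collapse adjacent identical states (possible only if two breakpoints
      # coincide numerically)
      keep <- c(TRUE, state[-1] != state[-length(state)])
      starts_k <- starts[keep]
      state_k <- state[keep]
      segs[[i]] <- data.frame(chrom = chrom, start = starts_k,
                              end = c(starts_k[-1], L), state = state_k)
      cos[[i]] <- if (length(starts_k) > 1)
        data.frame(chrom = chrom, pos = starts_k[-1])
      else data.frame(chrom = character(), pos = numeric())
    }
    list(id = sprintf("F2_%04d", idx),
         segments = do.call(rbind, segs),
         crossovers = do.call(rbind, cos))
  }
  structure(lapply(seq_len(n_individuals), one_individual),
            class = "f2_truth")
}

#' @export
print.f2_truth <- function(x, ...) {
  nco <- vapply(x, function(ind) nrow(ind$crossovers), 0L)
  cat(sprintf("f2_truth: %d individuals, mean %.1f crossovers each\n",
              length(x), mean(nco)))
  invisible(x)
}

#' True genotype states of simulated individuals at given sites
#'
#' @param truth an `f2_truth` object.
#' @param sites data.frame with `chrom`, `pos`.
#' @return Integer matrix (individuals x sites) with values 1 = AA, 2 = AB,
#'   3 = BB.
#' @export
true_genotypes <- function(truth, sites) {
  states <- c(AA = 1L, AB = 2L, BB = 3L)
  res <- vapply(truth, function(ind) {
    g <- integer(nrow(sites))
    for (chrom in unique(sites$chrom)) {
      sel <- sites$chrom == chrom
      seg <- ind$segments[ind$segments$chrom == chrom, ]
      if (nrow(seg) == 0) stop("site on chromosome absent from truth: ", chrom)
      idx <- findInterval(sites$pos[sel], seg$start, left.open = FALSE)
      idx[idx < 1] <- 1L
      g[sel] <- states[seg$state[idx]]
    }
    g
  }, integer(nrow(sites)))
  # vapply drops to a plain vector when there is a single site
  if (nrow(sites) == 1) matrix(res, ncol = 1) else t(res)
}

#' Simulate shallow-sequencing allele counts
#'
#' Per individual and variant site, sequencing depth is Poisson with the
#' given mean coverage and the ALT read count is binomial with success
#' probability `error_rate`, 0.5 or `1 - error_rate` for true genotype AA,
#' AB, BB.
#'
#' @param truth an `f2_truth` object.
#' @param variants a `parental_variants` data.frame (positions define the
#'   informative sites).
#' @param mean_coverage mean reads per site (> 0).
#' @param error_rate per-read error probability in `[0, 0.5)`.
#' @param seed integer seed.
#' @return An `allele_counts` object: list with `sites` (data.frame `chrom`,
#'   `pos`), `ref` and `alt` integer matrices (individuals x sites) and
#'   `sample_ids`.
#' @export
simulate_allele_counts <- function(truth, variants, mean_coverage,
                                   error_rate = 0.01, seed = NULL) {
  if (mean_coverage <= 0) stop("mean_coverage must be > 0")
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must be in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  sites <- data.frame(chrom = variants$chrom, pos = variants$pos)
  g <- true_genotypes(truth, sites)          # n x T in {1,2,3}
  n <- nrow(g); nT <- ncol(g)
  p_state <- c(error_rate, 0.5, 1 - error_rate)
  depth <- matrix(stats::rpois(n * nT, mean_coverage), n, nT)
  alt <- matrix(stats::rbinom(n * nT, depth, p_state[g]), n, nT)
  structure(list(sites = sites, ref = depth - alt, alt = alt,
                 sample_ids = vapply(truth, `[[`, "", "id")),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  depth <- x$ref + x$alt
  cat(sprintf("allele_counts: %d samples x %d sites, mean depth %.3f\n",
              length(x$sample_ids), nrow(x$sites), mean(depth)))
  invisible(x)
}

#' Specify additive/dominance QTL for trait simulation
#'
#' @param chrom,pos_bp QTL locations.
#' @param a additive effects in trait units: genotype contributions are
#'   `-a`, `d`, `+a` for AA, AB, BB (the A allele lowers the trait when
#'   `a > 0`).
#' @param d dominance effects (default 0).
#' @param residual_sd residual standard deviation (>= 0).
#' @param line_sd between-line standard deviation for replicated designs.
#' @param baseline trait baseline (default 30, days-to-flowering scale).
#' @return A `qtl_spec` list.
#' @export
qtl_spec <- function(chrom, pos_bp, a, d = 0, residual_sd = 1,
                     line_sd = 0, baseline = 30) {
  n <- length(chrom)
  d <- rep_len(d, n)
  stopifnot(length(pos_bp) == n, length(a) == n, residual_sd >= 0)
  structure(list(loci = data.frame(chrom = as.character(chrom),
                                   pos_bp = pos_bp, a = a, d = d),
                 residual_sd = residual_sd, line_sd = line_sd,
                 baseline = baseline),
            class = "qtl_spec")
}

#' Simulate phenotypes from planted QTL
#'
#' Phenotype of an individual is `baseline + sum over QTL of (-a, d, +a)`
#' for genotype AA, AB, BB at the QTL position, plus Normal(0, residual_sd)
#' noise.
#'
#' @param truth an `f2_truth` object.
#' @param qtl a `qtl_spec`.
#' @param seed integer seed.
#' @return data.frame with `id`, `phenotype`, and one genotype column per
#'   QTL (`qtl1`, `qtl2`, ... coded 1/2/3).
#' @export
simulate_phenotypes <- function(truth, qtl, seed = NULL) {
  stopifnot(inherits(qtl, "qtl_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(truth)
  y <- rep(qtl$baseline, n)
  out <- data.frame(id = vapply(truth, `[[`, "", "id"))
  if (nrow(qtl$loci) > 0) {
    g <- true_genotypes(truth, data.frame(chrom = qtl$loci$chrom,
                                          pos = qtl$loci$pos_bp))
    for (j in seq_len(nrow(qtl$loci))) {
      contrib <- c(-qtl$loci$a[j], qtl$loci$d[j], qtl$loci$a[j])
      y <- y + contrib[g[, j]]
      out[[paste0("qtl", j)]] <- g[, j]
    }
  }
  out$phenotype <- y + stats::rnorm(n, 0, qtl$residual_sd)
  out
}

#' Censor days-to-flowering at the end of an experiment
#'
#' Values above 125 days are recoded to exactly 130, the convention for
#' plants that had not flowered when scoring ended.
#'
#' @param dtf numeric vector of days to flowering.
#' @return Censored vector.
#' @export
censor_dtf <- function(dtf) {
  dtf[dtf > 125] <- 130
  dtf
}

#' Simulate a replicated-line phenotyping experiment
#'
#' Emulates a two-arm (control / vernalized) experiment on replicated inbred
#' lines: line effects are Normal(0, line_sd) around the baseline, replicate
#' noise is Normal(0, residual_sd), and the vernalized arm's expected value
#' is the control expectation times `vernalization_ratio` (after subtraction
#' of the cold period, i.e. values are on the comparable scale already).
#' Also generates a daily projected-rosette-area series with per-line
#' log-linear growth for growth-trajectory analysis.
#'
#' @param n_lines number of lines (>= 2 for heritability work).
#' @param reps_per_line replicates per line and arm (>= 2).
#' @param line_sd between-line SD in trait units.
#' @param residual_sd within-line SD.
#' @param vernalization_ratio multiplicative shift of the vernalized arm
#'   (0.5 halves the trait, giving log2 sensitivity 1).
#' @param baseline trait baseline (default 30).
#' @param growth_days days at which rosette area is recorded.
#' @param growth_rgr_mean,growth_rgr_sd mean and between-line SD of the true
#'   relative growth rate (per day).
#' @param seed integer seed.
#' @return List with `pheno` (data.frame `line`, `replicate`, `treatment`,
#'   `DTF`), `growth` (data.frame `line`, `replicate`, `day`, `area`) and
#'   `line_means` (true per-line control expectations).
#' @export
simulate_replicated_lines <- function(n_lines, reps_per_line, line_sd,
                                      residual_sd, vernalization_ratio = 0.5,
                                      baseline = 30,
                                      growth_days = 7:20,
                                      growth_rgr_mean = 0.25,
                                      growth_rgr_sd = 0.03,
                                      seed = NULL) {
  if (reps_per_line < 2) stop("reps_per_line must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  lines <- sprintf("L%03d", seq_len(n_lines))
  mu <- baseline + stats::rnorm(n_lines, 0, line_sd)
  arms <- data.frame(treatment = c("none", "vernalized"),
                     mult = c(1, vernalization_ratio))
  pheno <- do.call(rbind, lapply(seq_len(n_lines), function(i) {
    do.call(rbind, lapply(seq_len(nrow(arms)), function(k) {
      data.frame(line = lines[i], replicate = seq_len(reps_per_line),
                 treatment = arms$treatment[k],
                 DTF = mu[i] * arms$mult[k] +
                   stats::rnorm(reps_per_line, 0, residual_sd))
    }))
  }))
  rgr <- stats::rnorm(n_lines, growth_rgr_mean, growth_rgr_sd)
  a0 <- stats::rlnorm(n_lines, log(2000), 0.2)
  growth <- do.call(rbind, lapply(seq_len(n_lines), function(i) {
    do.call(rbind, lapply(seq_len(reps_per_line), function(r) {
      noise <- stats::rnorm(length(growth_days), 0, 0.05)
      data.frame(line = lines[i], replicate = r, day = growth_days,
                 area = a0[i] * exp(rgr[i] * growth_days + noise))
    }))
  }))
  list(pheno = pheno, growth = growth,
       line_means = stats::setNames(mu, lines))
}

#' Build a cross object directly from simulated truth
#'
#' Bypasses sequencing and HMM reconstruction: markers are placed at the
#' midpoints of the intervals induced by the union of all true crossover
#' breakpoints, and each individual's genotype at a marker is its true
#' segment state. Used to test mapping stages against exact genotypes.
#'
#' @param truth an `f2_truth` object.
#' @param genome the `genome_spec` the truth was simulated on.
#' @param pheno optional data.frame of phenotypes with an `id` column
#'   matching the individuals.
#' @return An `f2cross` (see [make_cross()]).
#' @export
cross_from_truth <- function(truth, genome, pheno = NULL) {
  chroms <- genome$chromosomes
  markers <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    chrom <- chroms$chrom[i]; L <- chroms$length_bp[i]
    bp <- sort(unique(unlist(lapply(truth, function(ind)
      ind$crossovers$pos[ind$crossovers$chrom == chrom]))))
    cuts <- c(0, bp, L)
    mid <- (cuts[-1] + cuts[-length(cuts)]) / 2
    data.frame(chrom = chrom, pos_bp = mid)
  }))
  g <- true_genotypes(truth, data.frame(chrom = markers$chrom,
                                        pos = markers$pos_bp))
  rownames(g) <- vapply(truth, `[[`, "", "id")
  make_cross(g, markers, genome, pheno = pheno)
}
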