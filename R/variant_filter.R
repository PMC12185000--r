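#' Hard soft-filter for parental variant calls
#'
#' Flags records failing the hard-filter expression
#' `QD < 5.0 || FS > 60.0 || MQ < 50.0 || MQRankSum < -12.5 ||
#' ReadPosRankSum < -8.0`. All comparisons are strict, so boundary values
#' pass; a missing annotation never triggers its clause.
#'
#' @param variants a `parental_variants` data.frame.
#' @return The input with `filter_status` set to `"soft_fail"` on failing
#'   records (records already failed upstream are left untouched).
#' @export
apply_soft_filter <- function(variants) {
  tr <- function(x, f) !is.na(x) & f(x)
  fail <- tr(variants$QD, function(x) x < 5.0) |
    tr(variants$FS, function(x) x > 60.0) |
    tr(variants$MQ, function(x) x < 50.0) |
    tr(variants$MQRankSum, function(x) x < -12.5) |
    tr(variants$ReadPosRankSum, function(x) x < -8.0)
  sel <- variants$filter_status == "pass" & fail
  variants$filter_status[sel] <- "soft_fail"
  variants
}

#' Fit a Gaussian (or two-component mixture) and derive a retention interval
#'
#' For `n_components = 2`, a two-component normal mixture is fitted by
#' expectation-maximization (k-means-style deterministic initialisation at
#' the 25%/75% quantiles, at most 100 iterations, log-likelihood tolerance
#' 1e-6); for `n_components = 1`, moment estimates are used. The retention
#' interval is centred on the dominant (largest-weight) component:
#' `[mean - k_sd * SD, mean + k_sd * SD]`.
#'
#' @param values numeric vector (>= 10 finite values).
#' @param n_components 1 or 2.
#' @param k_sd positive multiplier on the dominant component's SD.
#' @return A `gaussian_fit` list: `means`, `sds`, `weights`, `dominant`
#'   (component index), `interval` (length-2 numeric), `loglik`.
#' @export
fit_dominant_gaussian <- function(values, n_components = 2, k_sd = 2.5) {
  x <- values[is.finite(values)]
  if (length(x) < 10) stop("need at least 10 finite values")
  if (k_sd <= 0) stop("k_sd must be positive")
  sd_floor <- 1e-6
  if (n_components == 1) {
    m <- mean(x); s <- stats::sd(x)
    if (!is.finite(s) || s < sd_floor) {
      warning("degenerate values: SD floored at 1e-6")
      s <- sd_floor
    }
    fit <- list(means = m, sds = s, weights = 1, dominant = 1L,
                loglik = sum(stats::dnorm(x, m, s, log = TRUE)))
  } else if (n_components == 2) {
    if (stats::sd(x) < sd_floor) {
      warning("degenerate values: SD floored at 1e-6")
      fit <- list(means = rep(mean(x), 2), sds = rep(sd_floor, 2),
                  weights = c(1, 0), dominant = 1L, loglik = NA_real_)
    } else {
      init <- stats::kmeans(x, centers = matrix(stats::quantile(x, c(0.25, 0.75))))
      mu <- as.vector(init$centers)
      sg <- vapply(1:2, function(k) {
        s <- stats::sd(x[init$cluster == k])
        if (!is.finite(s) || s < sd_floor) sd_floor else s
      }, 0)
      w <- as.vector(table(factor(init$cluster, 1:2))) / length(x)
      ll_old <- -Inf
      for (it in 1:100) {
        dens <- vapply(1:2, function(k) w[k] * stats::dnorm(x, mu[k], sg[k]), x)
        tot <- rowSums(dens)
        tot[tot == 0] <- .Machine$double.xmin
        ll <- sum(log(tot))
        resp <- dens / tot
        nk <- colSums(resp)
        w <- nk / length(x)
        mu <- colSums(resp * x) / nk
        sg <- sqrt(colSums(resp * (x - rep(mu, each = length(x)))^2) / nk)
        sg[!is.finite(sg) | sg < sd_floor] <- sd_floor
        if (abs(ll - ll_old) < 1e-6) break
        ll_old <- ll
      }
      fit <- list(means = mu, sds = sg, weights = w,
                  dominant = which.max(w), loglik = ll)
    }
  } else stop("n_components must be 1 or 2")
  d <- fit$dominant
  fit$interval <- c(fit$means[d] - k_sd * fit$sds[d],
                    fit$means[d] + k_sd * fit$sds[d])
  fit$k_sd <- k_sd
  class(fit) <- "gaussian_fit"
  fit
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("gaussian_fit: %d component(s); dominant mean %.3f sd %.3f (w %.2f); interval [%.3f, %.3f]\n",
              length(x$means), x$means[x$dominant], x$sds[x$dominant],
              x$weights[x$dominant], x$interval[1], x$interval[2]))
  invisible(x)
}

# is a 1-based variant position inside any 0-based half-open BED interval?
.in_regions <- function(chrom, pos, bed) {
  if (is.null(bed) || nrow(bed) == 0) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(bed))) {
    hit <- hit | (chrom == bed$chrom[i] &
                    pos - 1 >= bed$start[i] & pos - 1 < bed$end[i])
  }
  hit
}

#' Automated corrected variant filter
#'
#' Applies the second filtering tier to soft-filter-passing records:
#' variants inside an exclusion region (centromere, telomere, transposable
#' element) are removed first (`region_fail`); on the remainder, a bimodal
#' Gaussian is fitted to QD and unimodal Gaussians to FS and MQRankSum, and
#' records outside the dominant-peak interval of QD (+- `k_qd` SD), the FS
#' interval (+- `k_fs` SD), the MQRankSum interval (+- `k_mqrs` SD) or with
#' MQ below the fixed `mq_min` are flagged `corrected_fail`. A record with
#' a missing annotation is retained for that metric.
#'
#' @param variants a `parental_variants` data.frame, already soft-filtered.
#' @param exclusion_bed optional data.frame (`chrom`, `start` 0-based,
#'   `end`, `class`) of excluded regions.
#' @param k_qd,k_fs,k_mqrs SD multipliers (defaults 2.5, 2.5, 4).
#' @param mq_min fixed mapping-quality threshold (default 50).
#' @param fits optional list of precomputed `gaussian_fit` objects (`QD`,
#'   `FS`, `MQRankSum`). Supplying the fits reapplies a frozen decision
#'   rule, which makes the filter exactly idempotent; refitting on
#'   already-filtered values would slightly tighten the intervals
#'   (truncation shrinks the SD estimates).
#' @return The input with updated `filter_status`; the fitted
#'   `gaussian_fit` objects are attached as attribute `"fits"`.
#' @export
corrected_filter <- function(variants, exclusion_bed = NULL,
                             k_qd = 2.5, k_fs = 2.5, k_mqrs = 4,
                             mq_min = 50, fits = NULL) {
  if (nrow(variants) == 0) {
    warning("empty variant input")
    return(variants)
  }
  live <- variants$filter_status == "pass"
  in_reg <- .in_regions(variants$chrom, variants$pos, exclusion_bed)
  variants$filter_status[live & in_reg] <- "region_fail"
  live <- variants$filter_status == "pass"

  if (is.null(fits))
    fits <- list(
      QD = fit_dominant_gaussian(variants$QD[live], 2, k_qd),
      FS = fit_dominant_gaussian(variants$FS[live], 1, k_fs),
      MQRankSum = fit_dominant_gaussian(variants$MQRankSum[live], 1, k_mqrs))
  outside <- function(x, iv) !is.na(x) & (x < iv[1] | x > iv[2])
  fail <- outside(variants$QD, fits$QD$interval) |
    outside(variants$FS, fits$FS$interval) |
    outside(variants$MQRankSum, fits$MQRankSum$interval) |
    (!is.na(variants$MQ) & variants$MQ < mq_min)
  variants$filter_status[live & fail] <- "corrected_fail"
  attr(variants, "fits") <- fits
  variants
}

#' Select biallelic SNPs and the ALT-source parent
#'
#' Keeps biallelic SNP records only (single-base REF and ALT; multiallelic
#' and indel records are flagged `non_biallelic`) and designates the parent
#' contributing the larger number of biallelic SNPs as the source of the
#' alternate allele (ties broken to parent 1). The chosen parent's variant
#' set is returned; `source_parent` orients downstream QTL effect signs.
#'
#' @param parent1,parent2 `parental_variants` data.frames (e.g. from
#'   [read_parent_vcf()]) or VCF paths.
#' @param labels character length-2 parent labels.
#' @return The ALT-source parent's `parental_variants`, with non-biallelic
#'   records flagged; attribute `"alt_parent"` holds the chosen label.
#' @export
select_biallelic_and_alt_parent <- function(parent1, parent2,
                                            labels = c("parent1", "parent2")) {
  load1 <- function(p, lab) {
    if (is.character(p)) p <- read_parent_vcf(p, source_parent = lab)
    p$source_parent <- lab
    p
  }
  p1 <- load1(parent1, labels[1])
  p2 <- load1(parent2, labels[2])
  flag_biallelic <- function(p) {
    ok <- nchar(p$ref) == 1 & nchar(p$alt) == 1 &
      p$ref %in% c("A", "C", "G", "T") & p$alt %in% c("A", "C", "G", "T") &
      !grepl(",", p$alt, fixed = TRUE)
    p$filter_status[p$filter_status == "pass" & !ok] <- "non_biallelic"
    p
  }
  p1 <- flag_biallelic(p1); p2 <- flag_biallelic(p2)
  n1 <- sum(p1$filter_status != "non_biallelic")
  n2 <- sum(p2$filter_status != "non_biallelic")
  if (n2 > n1) {
    chosen <- p2; lab <- labels[2]
  } else {
    if (n1 == n2) message("equal variant counts; ALT source tie broken to ", labels[1])
    chosen <- p1; lab <- labels[1]
  }
  attr(chosen, "alt_parent") <- lab
  chosen
}

#' Summarise filtering outcomes
#'
#' @param variants a `parental_variants` data.frame after filtering.
#' @return data.frame of counts per `filter_status`.
#' @export
filter_audit <- function(variants) {
  tab <- table(variants$filter_status)
  data.frame(status = names(tab), n = as.vector(tab))
}

#' Run the full two-tier variant filter
#'
#' Convenience wrapper: [apply_soft_filter()] then [corrected_filter()].
#' The retained (`"pass"`) records form the corrected marker file.
#'
#' @inheritParams corrected_filter
#' @return Filtered `parental_variants` with attributes `"fits"` and
#'   `"audit"`.
#' @export
filter_variants <- function(variants, exclusion_bed = NULL,
                            k_qd = 2.5, k_fs = 2.5, k_mqrs = 4, mq_min = 50,
                            fits = NULL) {
  v <- apply_soft_filter(variants)
  v <- corrected_filter(v, exclusion_bed, k_qd, k_fs, k_mqrs, mq_min,
                        fits = fits)
  attr(v, "audit") <- filter_audit(v)
  v
}
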