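#' Broad-sense heritability of a replicated-line trait
#'
#' Method-of-moments one-way random-effects decomposition: with mean
#' squares between (MSB) and within (MSW) lines and the unbalanced-design
#' effective replicate number `k0 = (N - sum(n_i^2)/N) / (g - 1)`, the
#' among-line variance is `(MSB - MSW)/k0` and
#' `H^2 = var_line / (var_line + var_error)`, clipped to `[0, 1]`.
#'
#' @param table data.frame with a `line` column and the trait column.
#' @param trait trait column name.
#' @return H-squared in `[0, 1]`.
#' @export
broad_sense_heritability <- function(table, trait) {
  y <- table[[trait]]
  ok <- !is.na(y)
  y <- y[ok]
  line <- factor(table$line[ok])
  g <- nlevels(line)
  if (g < 2) stop("heritability needs at least 2 lines")
  ni <- as.vector(table(line))
  if (any(ni < 2)) stop("every line needs at least 2 replicates")
  N <- length(y)
  means <- tapply(y, line, mean)
  ssb <- sum(ni * (means - mean(y))^2)
  ssw <- sum((y - means[line])^2)
  msb <- ssb / (g - 1)
  msw <- ssw / (N - g)
  k0 <- (N - sum(ni^2) / N) / (g - 1)
  var_line <- (msb - msw) / k0
  h2 <- var_line / (var_line + msw)
  min(max(h2, 0), 1)
}

#' Per-line vernalization sensitivity
#'
#' `log2(mean trait without vernalization / mean trait with vernalization)`
#' per line. Vernalized values are expected on the comparable scale (cold
#' period already subtracted on ingestion). Lines missing one arm are
#' skipped with a message.
#'
#' @param table data.frame with `line`, `treatment` (`"none"` /
#'   `"vernalized"`) and the trait column.
#' @param trait trait column name.
#' @return Named numeric vector of per-line log2 ratios.
#' @export
vernalization_sensitivity <- function(table, trait) {
  out <- c()
  for (ln in unique(table$line)) {
    a <- table[[trait]][table$line == ln & table$treatment == "none"]
    b <- table[[trait]][table$line == ln & table$treatment == "vernalized"]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) == 0 || length(b) == 0) {
      message("line ", ln, " lacks one treatment arm; skipped")
      next
    }
    out[ln] <- log2(mean(a) / mean(b))
  }
  out
}

#' Classify mutant lines as knockout or knockdown by expression
#'
#' A mutant line with mean relative expression below the cutoff (default
#' 5 a.u.) is a knockout (KO); at or above it, a knockdown (KD). Wild-type
#' rows are rejected: the classification applies to mutants only.
#'
#' @param table data.frame with `line`, `expression` and optionally
#'   `genotype_class`.
#' @param cutoff expression cutoff in arbitrary units (default 5).
#' @return Named character vector (`"KO"`/`"KD"`) per line.
#' @export
classify_ko_kd <- function(table, cutoff = 5) {
  if (!is.null(table$genotype_class) && any(table$genotype_class == "wildtype"))
    stop("classify_ko_kd applies to mutant lines only")
  means <- tapply(table$expression, table$line, mean, na.rm = TRUE)
  stats::setNames(ifelse(as.vector(means) < cutoff, "KO", "KD"),
                  names(means))
}

#' Pairwise Pearson correlations of trait line means
#'
#' Computes line means per trait, then all pairwise Pearson correlations
#' on the untransformed means with two-sided p-values on `n - 2` degrees
#' of freedom.
#'
#' @param table data.frame with `line` and the trait columns.
#' @param traits character vector of trait column names.
#' @return list with matrices `r`, `p`, `df`, and `n` (lines used per pair).
#' @export
trait_correlations <- function(table, traits) {
  means <- do.call(cbind, lapply(traits, function(tr)
    tapply(table[[tr]], table$line, mean, na.rm = TRUE)))
  colnames(means) <- traits
  k <- length(traits)
  r <- p <- dfm <- nm <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(means[, c(i, j)])
    n <- sum(ok)
    nm[i, j] <- n
    if (n < 3) {
      warning("fewer than 3 lines for ", traits[i], " vs ", traits[j])
      next
    }
    if (i == j) {
      r[i, j] <- 1; p[i, j] <- 0; dfm[i, j] <- n - 2
    } else {
      ct <- stats::cor.test(means[ok, i], means[ok, j], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
      dfm[i, j] <- unname(ct$parameter)
    }
  }
  list(r = r, p = p, df = dfm, n = nm)
}

#' Mutant-versus-wild-type contrasts with multiplicity control
#'
#' One two-group test per contrast: a Mann-Whitney U rank test (exact when
#' both sides have at most 8 values and no ties, normal approximation with
#' continuity correction otherwise) or a two-sided Student's t test.
#' Raw p-values are adjusted by Benjamini-Hochberg, Bonferroni, or not at
#' all. Zero-variance t-test input is handled by the degenerate rule:
#' equal means give p = 1, unequal means p = 0 with a warning.
#'
#' @param values numeric vector of measurements.
#' @param side factor/character with two levels (e.g. mutant / wildtype)
#'   aligned with `values`.
#' @param contrast contrast identifier aligned with `values` (e.g. the
#'   wild-type accession of each mutant pair).
#' @param test `"mann_whitney"` or `"t_two_sided"`.
#' @param correction `"benjamini_hochberg"`, `"bonferroni"` or `"none"`.
#' @param alpha significance level for the flag column (default 0.05).
#' @return data.frame `contrast`, `statistic`, `p`, `p_adj`, `direction`
#'   (sign of first-level mean minus second-level mean), `significant`.
#' @export
pairwise_contrasts <- function(values, side, contrast,
                               test = c("mann_whitney", "t_two_sided"),
                               correction = c("benjamini_hochberg",
                                              "bonferroni", "none"),
                               alpha = 0.05) {
  test <- match.arg(test)
  correction <- match.arg(correction)
  side <- factor(side)
  if (nlevels(side) != 2) stop("side must have exactly two levels")
  ids <- unique(contrast)
  res <- lapply(ids, function(id) {
    x <- values[contrast == id & side == levels(side)[1]]
    y <- values[contrast == id & side == levels(side)[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (test == "mann_whitney") {
      if (length(unique(c(x, y))) == 1) {
        # every value tied: the tie-corrected normal approximation is 0/0
        stat <- length(x) * length(y) / 2; pv <- 1
      } else {
        ties <- any(duplicated(c(x, y)))
        exact <- length(x) <= 8 && length(y) <= 8 && !ties
        wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                                  correct = TRUE))
        stat <- unname(wt$statistic); pv <- wt$p.value
      }
    } else {
      if (length(x) < 2 || length(y) < 2)
        stop("t test needs at least 2 values per side in contrast ", id)
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        if (mean(x) == mean(y)) {
          stat <- 0; pv <- 1
        } else {
          warning("zero-variance groups with unequal means in contrast ", id)
          stat <- Inf; pv <- 0
        }
      } else {
        tt <- stats::t.test(x, y)
        stat <- unname(tt$statistic); pv <- tt$p.value
      }
    }
    data.frame(contrast = id, statistic = stat, p = pv,
               direction = sign(mean(x) - mean(y)))
  })
  out <- do.call(rbind, res)
  meth <- c(benjamini_hochberg = "BH", bonferroni = "bonferroni",
            none = "none")[correction]
  out$p_adj <- stats::p.adjust(out$p, method = meth)
  out$significant <- out$p_adj < alpha
  out[, c("contrast", "statistic", "p", "p_adj", "direction", "significant")]
}

#' Relative expression by the delta-delta-Ct method
#'
#' `rel = 2^(-ddCt)` with
#' `ddCt = (Ct_target - Ct_reference) - (Ct_target - Ct_reference)[calibrator]`.
#' The conventional calibrator is biological replicate 1 of the reference
#' accession. Samples with a missing reference Ct yield NA.
#'
#' @param ct_target target-gene Ct values.
#' @param ct_reference reference-gene (e.g. ACT8) Ct values, aligned.
#' @param calibrator index (or logical) of the calibrator sample(s); if
#'   several, their mean delta-Ct is used.
#' @return Numeric vector of relative expression in arbitrary units.
#' @export
delta_delta_ct <- function(ct_target, ct_reference, calibrator = 1) {
  dct <- ct_target - ct_reference
  cal <- mean(dct[calibrator], na.rm = TRUE)
  if (!is.finite(cal)) stop("calibrator delta-Ct is missing")
  2^(-(dct - cal))
}

# linear interpolation of missing interior days; ends are not extrapolated.
.interp_series <- function(day, value, days_all) {
  out <- rep(NA_real_, length(days_all))
  ok <- !is.na(value)
  if (sum(ok) >= 2) {
    ap <- stats::approx(day[ok], value[ok], xout = days_all, rule = 1)
    out <- ap$y
  } else if (sum(ok) == 1) {
    out[days_all == day[ok]] <- value[ok]
  }
  out
}

#' Growth-trajectory analysis of projected rosette area
#'
#' Applies the pixel exclusion rules (plants below `min_pixels_any` on any
#' day in the analysis range, or below `min_pixels_late` in the late stage
#' - by default the final third of measured days - are excluded), computes
#' the relative growth rate `RGR = (ln A_end - ln A_start) / (end - start)`
#' per plant, runs per-day mutant-versus-wild-type contrasts, and clusters
#' the mutants' daily `log2(mutant mean / wild-type mean)` trajectory
#' vectors hierarchically (Ward linkage on Euclidean distance) into `k`
#' groups. Missing interior days are linearly interpolated per line; ends
#' are not extrapolated.
#'
#' @param table data.frame with `line`, `replicate`, `day`, `area` (pixels).
#' @param pairs data.frame with columns `mutant` and `wildtype` giving the
#'   line pairing.
#' @param day_range length-2 vector: RGR start and end days (default 11, 18).
#' @param k number of trajectory clusters (default 3).
#' @param min_pixels_any,min_pixels_late exclusion thresholds (500, 5000).
#' @param test,correction passed to [pairwise_contrasts()] for the per-day
#'   tests.
#' @return list with `rgr` (per plant), `excluded` (plants and reasons),
#'   `per_day` (contrast table per day), `trajectories` (mutants x days
#'   log2-ratio matrix) and `clusters` (named cluster assignment).
#' @export
growth_analysis <- function(table, pairs, day_range = c(11, 18), k = 3,
                            min_pixels_any = 500, min_pixels_late = 5000,
                            test = "mann_whitney",
                            correction = "benjamini_hochberg") {
  stopifnot(all(c("line", "replicate", "day", "area") %in% names(table)))
  if (any(table$area <= 0, na.rm = TRUE)) stop("areas must be positive")
  days_all <- sort(unique(table$day))
  late_days <- days_all[days_all >= days_all[ceiling(2 * length(days_all) / 3)]]
  plant_id <- interaction(table$line, table$replicate, drop = TRUE)
  in_range <- table$day >= day_range[1] & table$day <= day_range[2]
  excl <- vapply(levels(plant_id), function(pid) {
    sel <- plant_id == pid
    if (any(table$area[sel & in_range] < min_pixels_any, na.rm = TRUE))
      return("below 500 px in range")
    if (any(sel & table$day %in% late_days) &&
        all(table$area[sel & table$day %in% late_days] < min_pixels_late,
            na.rm = TRUE))
      return("below 5000 px in late stage")
    ""
  }, "")
  excluded <- data.frame(plant = names(excl)[excl != ""],
                         reason = excl[excl != ""], row.names = NULL)
  keep <- plant_id %in% names(excl)[excl == ""]
  tb <- table[keep, , drop = FALSE]

  # per-plant RGR
  pid <- interaction(tb$line, tb$replicate, drop = TRUE)
  rgr <- do.call(rbind, lapply(levels(pid), function(p) {
    sel <- pid == p
    a1 <- tb$area[sel & tb$day == day_range[1]]
    a2 <- tb$area[sel & tb$day == day_range[2]]
    data.frame(line = tb$line[sel][1], replicate = tb$replicate[sel][1],
               rgr = if (length(a1) == 1 && length(a2) == 1)
                 (log(a2) - log(a1)) / diff(day_range) else NA_real_)
  }))

  # daily line means (log scale under the hood, reported as ratios)
  line_day_mean <- function(ln) {
    sel <- tb$line == ln
    m <- tapply(tb$area[sel], tb$day[sel], mean)
    .interp_series(as.numeric(names(m)), as.vector(m), days_all)
  }
  traj <- t(vapply(seq_len(nrow(pairs)), function(i) {
    log2(line_day_mean(pairs$mutant[i]) / line_day_mean(pairs$wildtype[i]))
  }, numeric(length(days_all))))
  rownames(traj) <- pairs$mutant
  colnames(traj) <- days_all

  # per-day contrasts across all pairs
  per_day <- do.call(rbind, lapply(days_all, function(d) {
    sel <- tb$day == d & (tb$line %in% pairs$mutant | tb$line %in% pairs$wildtype)
    if (!any(sel)) return(NULL)
    sub <- tb[sel, ]
    m <- match(sub$line, pairs$mutant)
    w <- match(sub$line, pairs$wildtype)
    ctr <- ifelse(!is.na(m), as.character(pairs$mutant[m]),
                  as.character(pairs$mutant[w]))
    sd_side <- ifelse(!is.na(m), "mutant", "wildtype")
    ok <- !is.na(ctr)
    cc <- pairwise_contrasts(sub$area[ok], sd_side[ok], ctr[ok],
                             test = test, correction = correction)
    cbind(day = d, cc)
  }))

  # Ward clustering of trajectory vectors; columns with any NA are dropped
  # from the distance (ends not extrapolated)
  usable <- colSums(is.na(traj)) == 0
  clusters <- NULL
  if (nrow(traj) >= k && sum(usable) >= 2) {
    hc <- stats::hclust(stats::dist(traj[, usable, drop = FALSE]),
                        method = "ward.D2")
    clusters <- stats::cutree(hc, k = k)
  }
  list(rgr = rgr, excluded = excluded, per_day = per_day,
       trajectories = traj, clusters = clusters)
}
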