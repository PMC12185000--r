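#' Conditional genotype probabilities on a pseudomarker grid
#'
#' Computes P(genotype | all marker data) at every marker and at grid
#' positions every `step_cm` centimorgan, by forward-backward over a
#' three-state HMM along each chromosome: transitions follow the F2
#' two-locus matrix at Haldane recombination fractions, observed marker
#' genotypes emit their state with probability `1 - error_prob` (a small
#' genotyping-error allowance), and missing genotypes or pseudomarker
#' positions emit uniformly, so missing data are handled by summing over
#' states with their conditional weights.
#'
#' @param cross an `f2cross` with an estimated genetic map.
#' @param step_cm pseudomarker grid step in cM (default 2).
#' @param error_prob genotyping error probability (default 1e-4).
#' @return A `genoprob` object: list with `positions` (data.frame `chrom`,
#'   `pos_cm`, `pos_bp`, `is_marker`, `marker_id`) and `prob` (array
#'   individuals x positions x 3).
#' @export
calc_genoprob <- function(cross, step_cm = 2, error_prob = 1e-4) {
  if (anyNA(cross$markers$cm))
    stop("genetic map missing; run estimate_genetic_map() first")
  n <- nrow(cross$geno)
  pos_list <- list(); prob_list <- list()
  for (chrom in unique(cross$markers$chrom)) {
    sel <- which(cross$markers$chrom == chrom)
    mcm <- cross$markers$cm[sel]
    mbp <- cross$markers$pos_bp[sel]
    grid <- if (max(mcm) - min(mcm) > step_cm)
      setdiff(seq(min(mcm), max(mcm), by = step_cm), mcm) else numeric(0)
    all_cm <- c(mcm, grid)
    src <- c(sel, rep(NA_integer_, length(grid)))     # marker index or NA
    ord <- order(all_cm, is.na(src))                  # markers first on ties
    all_cm <- all_cm[ord]; src <- src[ord]
    is_mark <- !is.na(src)
    all_bp <- rep(NA_real_, length(all_cm))
    all_bp[is_mark] <- cross$markers$pos_bp[src[is_mark]]
    if (any(!is_mark)) {
      if (length(unique(mcm)) >= 2)
        all_bp[!is_mark] <- stats::approx(mcm, mbp, xout = all_cm[!is_mark],
                                          rule = 2, ties = "ordered")$y
      else all_bp[!is_mark] <- mbp[1]
    }
    P <- length(all_cm)
    # emissions
    emis <- vector("list", P)
    for (t in seq_len(P)) {
      e <- matrix(1, n, 3)
      if (is_mark[t]) {
        g <- cross$geno[, src[t]]
        obs <- !is.na(g)
        if (any(obs)) {
          e[obs, ] <- error_prob / 2
          e[cbind(which(obs), g[obs])] <- 1 - error_prob
        }
      }
      emis[[t]] <- e
    }
    trans <- lapply(haldane_r(diff(all_cm)), f2_transition)
    prior <- c(0.25, 0.5, 0.25)
    # scaled forward-backward
    alpha <- vector("list", P)
    a <- emis[[1]] * rep(prior, each = n)
    alpha[[1]] <- a / rowSums(a)
    if (P > 1) for (t in 2:P) {
      a <- (alpha[[t - 1]] %*% trans[[t - 1]]) * emis[[t]]
      alpha[[t]] <- a / rowSums(a)
    }
    beta <- matrix(1, n, 3)
    post <- array(0, c(n, P, 3))
    g <- alpha[[P]] * beta
    post[, P, ] <- g / rowSums(g)
    if (P > 1) for (t in (P - 1):1) {
      b <- (beta * emis[[t + 1]]) %*% t(trans[[t]])
      beta <- b / rowSums(b)
      g <- alpha[[t]] * beta
      post[, t, ] <- g / rowSums(g)
    }
    pos_list[[chrom]] <- data.frame(
      chrom = chrom, pos_cm = all_cm, pos_bp = all_bp, is_marker = is_mark,
      marker_id = ifelse(is_mark, cross$markers$id[src], NA_character_))
    prob_list[[chrom]] <- post
  }
  positions <- do.call(rbind, pos_list)
  rownames(positions) <- NULL
  prob <- array(0, c(n, nrow(positions), 3))
  off <- 0
  for (chrom in names(prob_list)) {
    P <- dim(prob_list[[chrom]])[2]
    prob[, off + seq_len(P), ] <- prob_list[[chrom]]
    off <- off + P
  }
  np <- dim(prob)[1:2]
  structure(list(positions = positions, prob = prob,
                 # additive and dominance predictors (kept as matrices even
                 # for a single evaluation position)
                 xa = matrix(prob[, , 3] - prob[, , 1], np[1], np[2]),
                 xd = matrix(prob[, , 2], np[1], np[2]),
                 ids = rownames(cross$geno)),
            class = "genoprob")
}

# LOD scores at every position for one or more phenotype columns.
# Y: n x k matrix (no missing values). Returns P x k matrix.
# Haley-Knott: regress Y on additive (pBB - pAA) and dominance (pAB)
# predictors; LOD = (n/2) log10(RSS0 / RSS1) with RSS1 floored at
# 1e-12 * TSS to stay finite on noiseless fixtures.
.scan_lod <- function(gp, Y, keep = NULL) {
  if (is.null(keep)) keep <- seq_len(dim(gp$prob)[1])
  Y <- as.matrix(Y)
  n <- nrow(Y)
  P <- nrow(gp$positions)
  ybar <- colMeans(Y)
  tss <- colSums(Y^2) - n * ybar^2
  lod <- matrix(0, P, ncol(Y))
  if (all(tss == 0)) return(lod)
  for (t in seq_len(P)) {
    qx <- qr(cbind(1, gp$xa[keep, t], gp$xd[keep, t]))
    fitted_ss <- colSums(qr.qty(qx, Y)[seq_len(qx$rank), , drop = FALSE]^2)
    rss1 <- pmax(colSums(Y^2) - fitted_ss, 1e-12 * pmax(tss, 1))
    lod[t, ] <- (n / 2) * log10(tss / rss1)
  }
  lod[, tss == 0] <- 0
  lod
}

#' Single-QTL genome scan by Haley-Knott regression
#'
#' At each marker and pseudomarker position the phenotype is regressed on
#' the conditional-expectation additive and dominance predictors; the LOD
#' score is `(n/2) log10(RSS0/RSS1)` against the intercept-only null.
#'
#' @param cross an `f2cross` with phenotypes and a genetic map.
#' @param trait phenotype column name.
#' @param step_cm pseudomarker step (default 2 cM).
#' @param genoprobs optional precomputed [calc_genoprob()] result.
#' @return A `qtl_scan` data.frame: `chrom`, `pos_cm`, `pos_bp`,
#'   `is_marker`, `lod`; attributes `trait`, `n`, `genoprob`.
#' @export
hk_scan <- function(cross, trait, step_cm = 2, genoprobs = NULL) {
  if (is.null(genoprobs)) genoprobs <- calc_genoprob(cross, step_cm)
  y <- cross$pheno[[trait]]
  if (is.null(y)) stop("trait not found: ", trait)
  keep <- which(!is.na(y))
  if (length(keep) < 30)
    warning("fewer than 30 individuals with trait values")
  y <- y[keep]
  if (stats::var(y) == 0) warning("constant phenotype: all LOD scores are 0")
  lod <- .scan_lod(genoprobs, matrix(y), keep = keep)
  out <- cbind(genoprobs$positions[, c("chrom", "pos_cm", "pos_bp", "is_marker")],
               lod = lod[, 1])
  class(out) <- c("qtl_scan", "data.frame")
  attr(out, "trait") <- trait
  attr(out, "n") <- length(keep)
  attr(out, "genoprob") <- genoprobs
  attr(out, "keep") <- keep
  out
}

#' Genome-wide LOD significance threshold by permutation
#'
#' The phenotype vector is permuted against the genotype matrix (rows
#' permuted jointly, preserving marker correlation), the genome-wide
#' maximum LOD is recorded for each permutation, and the threshold is the
#' empirical `1 - alpha` quantile of that null distribution.
#'
#' @param cross an `f2cross`.
#' @param trait phenotype column name.
#' @param n_perm number of permutations (1000 for production scans).
#' @param alpha genome-wide significance level (default 0.05).
#' @param seed integer seed for the permutations.
#' @param step_cm pseudomarker step.
#' @param genoprobs optional precomputed [calc_genoprob()] result.
#' @return The threshold (numeric); the max-LOD distribution is attached
#'   as attribute `"max_lods"`.
#' @export
permutation_threshold <- function(cross, trait, n_perm = 1000, alpha = 0.05,
                                  seed = NULL, step_cm = 2, genoprobs = NULL) {
  if (is.null(genoprobs)) genoprobs <- calc_genoprob(cross, step_cm)
  if (!is.null(seed)) set.seed(seed)
  y <- cross$pheno[[trait]]
  keep <- which(!is.na(y))
  y <- y[keep]
  Y <- vapply(seq_len(n_perm), function(i) sample(y), y)
  lod <- .scan_lod(genoprobs, Y, keep = keep)
  max_lods <- apply(lod, 2, max)
  thr <- unname(stats::quantile(max_lods, 1 - alpha))
  attr(thr, "max_lods") <- max_lods
  attr(thr, "alpha") <- alpha
  thr
}

#' Two-locus genome scan
#'
#' For every pair of distinct grid positions, fits the full two-QTL model
#' (both loci plus their four interaction terms) and the additive two-QTL
#' model by the same Haley-Knott machinery. The interaction LOD is
#' `LOD_full - LOD_add`; its significance threshold is the `1 - alpha`
#' quantile of the permuted genome-wide maximum interaction LOD.
#'
#' @param cross an `f2cross`.
#' @param trait phenotype column name.
#' @param n_perm permutations for the interaction threshold (default 100).
#' @param alpha significance level (default 0.05).
#' @param step_cm grid step; pairs scale quadratically, so the default is a
#'   coarse 10 cM.
#' @param seed integer seed.
#' @return A `scan_two` list: `pairs` (data.frame with per-pair full,
#'   additive and interaction LOD), `int_threshold`, and `interactions`
#'   (pairs exceeding the threshold).
#' @export
scan_two <- function(cross, trait, n_perm = 100, alpha = 0.05,
                     step_cm = 10, seed = NULL) {
  gp <- calc_genoprob(cross, step_cm)
  if (!is.null(seed)) set.seed(seed)
  y <- cross$pheno[[trait]]
  keep <- which(!is.na(y))
  y <- y[keep]
  n <- length(y)
  Y <- cbind(y, vapply(seq_len(n_perm), function(i) sample(y), y))
  tss <- colSums(Y^2) - n * colMeans(Y)^2
  # evaluate pairs on the coarse grid only: keep one position per step_cm
  # bin per chromosome (probabilities still condition on all markers)
  sub <- unlist(lapply(unique(gp$positions$chrom), function(ch) {
    sel <- which(gp$positions$chrom == ch)
    bins <- floor(gp$positions$pos_cm[sel] / step_cm)
    sel[!duplicated(bins)]
  }))
  gp$positions <- gp$positions[sub, , drop = FALSE]
  gp$xa <- gp$xa[, sub, drop = FALSE]
  gp$xd <- gp$xd[, sub, drop = FALSE]
  P <- nrow(gp$positions)
  xa <- gp$xa[keep, , drop = FALSE]
  xd <- gp$xd[keep, , drop = FALSE]
  pair_idx <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  # same-position pairs cannot arise from upper.tri; also drop pairs closer
  # than one grid step on the same chromosome to avoid collinear designs
  chr <- gp$positions$chrom; cmv <- gp$positions$pos_cm
  ok <- !(chr[pair_idx[, 1]] == chr[pair_idx[, 2]] &
            abs(cmv[pair_idx[, 1]] - cmv[pair_idx[, 2]]) < step_cm)
  pair_idx <- pair_idx[ok, , drop = FALSE]
  lod_of_rss <- function(rss) (n / 2) * log10(tss / pmax(rss, 1e-12 * pmax(tss, 1)))
  fit_rss <- function(X) {
    qx <- qr(X)
    colSums(Y^2) - colSums(qr.qty(qx, Y)[seq_len(qx$rank), , drop = FALSE]^2)
  }
  n_pairs <- nrow(pair_idx)
  lod_full <- matrix(0, n_pairs, ncol(Y))
  lod_add <- matrix(0, n_pairs, ncol(Y))
  for (k in seq_len(n_pairs)) {
    i <- pair_idx[k, 1]; j <- pair_idx[k, 2]
    Xa <- cbind(1, xa[, i], xd[, i], xa[, j], xd[, j])
    Xf <- cbind(Xa, xa[, i] * xa[, j], xa[, i] * xd[, j],
                xd[, i] * xa[, j], xd[, i] * xd[, j])
    lod_add[k, ] <- lod_of_rss(fit_rss(Xa))
    lod_full[k, ] <- lod_of_rss(fit_rss(Xf))
  }
  lod_int <- lod_full - lod_add
  int_thr <- unname(stats::quantile(apply(lod_int[, -1, drop = FALSE], 2, max),
                                    1 - alpha))
  pairs <- data.frame(chrom1 = chr[pair_idx[, 1]], pos1_cm = cmv[pair_idx[, 1]],
                      chrom2 = chr[pair_idx[, 2]], pos2_cm = cmv[pair_idx[, 2]],
                      lod_full = lod_full[, 1], lod_add = lod_add[, 1],
                      lod_int = lod_int[, 1])
  structure(list(pairs = pairs, int_threshold = int_thr,
                 interactions = pairs[pairs$lod_int > int_thr, , drop = FALSE],
                 trait = trait, n_perm = n_perm, alpha = alpha),
            class = "scan_two")
}

# design matrix / RSS of the additive multiple-QTL model with QTL at
# position indices qidx.
.multi_design <- function(gp, keep, qidx) {
  X <- matrix(1, length(keep), 1)
  for (q in qidx)
    X <- cbind(X, gp$xa[keep, q], gp$xd[keep, q])
  X
}

.multi_rss <- function(gp, keep, y, qidx) {
  qx <- qr(.multi_design(gp, keep, qidx))
  sum(y^2) - sum(qr.qty(qx, y)[seq_len(qx$rank)]^2)
}

# model LOD of adding each grid position to the current model, in closed
# form: candidate additive/dominance columns are residualized against the
# current design and the 2x2 normal equations solved per position.
.forward_lods <- function(gp, keep, y, cur, tss, A, D) {
  n <- length(y)
  q0 <- qr(.multi_design(gp, keep, cur))
  Q0 <- qr.Q(q0)[, seq_len(q0$rank), drop = FALSE]
  ry <- y - Q0 %*% crossprod(Q0, y)
  rss_cur <- sum(ry^2)
  RA <- A - Q0 %*% crossprod(Q0, A)
  RD <- D - Q0 %*% crossprod(Q0, D)
  aa <- colSums(RA^2); dd <- colSums(RD^2); ad <- colSums(RA * RD)
  ay <- as.vector(crossprod(RA, ry)); dy <- as.vector(crossprod(RD, ry))
  det <- aa * dd - ad^2
  ss <- (dd * ay^2 - 2 * ad * ay * dy + aa * dy^2) / det
  one <- pmax(ifelse(aa > 0, ay^2 / aa, 0), ifelse(dd > 0, dy^2 / dd, 0))
  bad <- !is.finite(ss) | det <= 1e-10 * pmax(aa * dd, .Machine$double.xmin)
  ss[bad] <- one[bad]
  ss <- pmin(pmax(ss, 0), rss_cur)
  rss_new <- rss_cur - ss
  (n / 2) * log10(tss / pmax(rss_new, 1e-12 * max(tss, 1)))
}

#' Stepwise selection of an additive multiple-QTL model
#'
#' Forward search adds, at each step, the grid position maximizing the
#' model LOD; after each addition, backward elimination drops any QTL whose
#' removal improves the penalized LOD `pLOD = LOD - penalty * nQTL`. The
#' model space is additive only (each QTL contributes additive and
#' dominance terms, no epistasis). The model with maximal pLOD over the
#' whole search is returned; an empty model (pLOD 0) is a valid result.
#'
#' @param cross an `f2cross`.
#' @param trait phenotype column name.
#' @param penalty per-QTL penalty on the LOD scale; conventionally the
#'   trait's own single-scan permutation threshold.
#' @param max_qtl maximum number of QTL in the forward search (default 8).
#' @param step_cm pseudomarker step.
#' @param genoprobs optional precomputed [calc_genoprob()] result.
#' @return A `qtl_model` list: `qtl` (data.frame `chrom`, `pos_cm`,
#'   `pos_bp`), `lod`, `plod`, `penalty`, `trait`.
#' @export
stepwise_additive <- function(cross, trait, penalty, max_qtl = 8,
                              step_cm = 2, genoprobs = NULL) {
  if (is.null(genoprobs)) genoprobs <- calc_genoprob(cross, step_cm)
  gp <- genoprobs
  y <- cross$pheno[[trait]]
  keep <- which(!is.na(y))
  y <- y[keep]
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  P <- nrow(gp$positions)
  lod_of <- function(qidx) {
    if (length(qidx) == 0) return(0)
    rss <- .multi_rss(gp, keep, y, qidx)
    (n / 2) * log10(tss / max(rss, 1e-12 * max(tss, 1)))
  }
  plod_of <- function(qidx) lod_of(qidx) - penalty * length(qidx)
  A <- gp$xa[keep, , drop = FALSE]
  D <- gp$xd[keep, , drop = FALSE]
  best <- list(qidx = integer(0), plod = 0)
  note <- function(qidx) {
    pl <- plod_of(qidx)
    if (pl > best$plod) best <<- list(qidx = qidx, plod = pl)
  }
  # forward phase: grow to max_qtl, recording the penalized LOD of every
  # visited model
  cur <- integer(0)
  while (length(cur) < max_qtl) {
    cand_lod <- .forward_lods(gp, keep, y, cur, tss, A, D)
    cand_lod[cur] <- -Inf
    cur <- c(cur, which.max(cand_lod))
    note(cur)
  }
  # backward phase: shrink to empty, always dropping the QTL whose removal
  # costs the least model LOD
  while (length(cur) > 1) {
    drop_lod <- vapply(seq_along(cur), function(k) lod_of(cur[-k]), 0)
    cur <- cur[-which.max(drop_lod)]
    note(cur)
  }
  qidx <- sort(best$qidx)
  qtl <- gp$positions[qidx, c("chrom", "pos_cm", "pos_bp"), drop = FALSE]
  rownames(qtl) <- NULL
  structure(list(qtl = qtl, qidx = qidx, lod = lod_of(qidx),
                 plod = best$plod, penalty = penalty, trait = trait,
                 genoprob = gp, keep = keep),
            class = "qtl_model")
}

#' @export
print.qtl_model <- function(x, ...) {
  cat(sprintf("qtl_model (%s): %d QTL, LOD %.2f, pLOD %.2f (penalty %.2f)\n",
              x$trait, nrow(x$qtl), x$lod, x$plod, x$penalty))
  if (nrow(x$qtl) > 0) print(x$qtl)
  invisible(x)
}

#' 95% Bayes credible interval for a QTL peak
#'
#' `10^LOD` is normalized over the chromosome's evaluation grid; positions
#' are accumulated from the highest mass down until the target coverage is
#' reached, the enclosing contiguous run is taken, and the interval is
#' expanded outward to the flanking genotyped markers. Reported in bp.
#'
#' @param scan a `qtl_scan` from [hk_scan()].
#' @param chrom chromosome of the peak.
#' @param coverage posterior mass to cover (default 0.95).
#' @return Numeric `c(lo_bp, hi_bp)`, with the cM interval as attribute
#'   `"interval_cm"`.
#' @export
bayes_interval <- function(scan, chrom, coverage = 0.95) {
  sel <- which(scan$chrom == chrom)
  if (length(sel) < 2) stop("need at least 2 scan positions on ", chrom)
  w <- 10^scan$lod[sel]
  w <- w / sum(w)
  if (max(w) - min(w) < 1e-12) {
    warning("flat LOD profile: interval spans the whole chromosome")
    picked <- seq_along(sel)
  } else {
    ord <- order(w, decreasing = TRUE)
    k <- which(cumsum(w[ord]) >= coverage)[1]
    picked <- ord[seq_len(k)]
  }
  lo <- min(picked); hi <- max(picked)
  # expand strictly outward to the flanking genotyped markers on each side
  is_mark <- scan$is_marker[sel]
  left_marks <- which(is_mark & seq_along(sel) < lo)
  right_marks <- which(is_mark & seq_along(sel) > hi)
  lo <- if (length(left_marks)) max(left_marks) else lo
  hi <- if (length(right_marks)) min(right_marks) else hi
  out <- c(scan$pos_bp[sel[lo]], scan$pos_bp[sel[hi]])
  attr(out, "interval_cm") <- c(scan$pos_cm[sel[lo]], scan$pos_cm[sel[hi]])
  out
}

#' Signed additive effects and explained variance of a QTL model
#'
#' Fits the additive multiple-QTL model at the model's positions and
#' reports, per QTL, the additive effect signed so that a positive value
#' means the early parent's allele promotes flowering (reduces the trait):
#' `a = (mean late-parent homozygote - mean early-parent homozygote) / 2`.
#' Per-QTL explained variance (PEV) is the drop-one residual-sum-of-squares
#' share `100 (RSS_without - RSS_full) / TSS`; the model PEV is
#' `100 (1 - RSS_full / TSS)`.
#'
#' @param cross an `f2cross` (supplies the phenotype).
#' @param model a `qtl_model` from [stepwise_additive()].
#' @param early_parent which genotype class, `"A"` or `"B"`, is the
#'   early-flowering parent's homozygote.
#' @return The model with `qtl` gaining columns `a`, `d`, `pev`, and
#'   elements `model_pev`, `early_parent`.
#' @export
qtl_effects <- function(cross, model, early_parent = c("A", "B")) {
  early_parent <- match.arg(early_parent)
  gp <- model$genoprob
  y <- cross$pheno[[model$trait]][model$keep]
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  qidx <- model$qidx
  if (length(qidx) == 0) {
    model$model_pev <- 0
    model$early_parent <- early_parent
    return(model)
  }
  X <- .multi_design(gp, model$keep, qidx)
  fit <- stats::lm.fit(X, y)
  rss_full <- sum(fit$residuals^2)
  coefs <- fit$coefficients
  a_raw <- coefs[seq(2, length(coefs), by = 2)]    # (mu_BB - mu_AA) / 2
  d_raw <- coefs[seq(3, length(coefs), by = 2)]
  sign_flip <- if (early_parent == "A") 1 else -1
  # trait-reducing early allele gives positive a under the convention
  a_signed <- sign_flip * a_raw
  pev <- vapply(seq_along(qidx), function(k) {
    drop_cols <- c(2 * k, 2 * k + 1)
    rss_wo <- .multi_rss(gp, model$keep, y, qidx[-k])
    100 * (rss_wo - rss_full) / tss
  }, 0)
  model$qtl$a <- unname(a_signed)
  model$qtl$d <- unname(d_raw)
  model$qtl$pev <- pev
  model$model_pev <- 100 * (1 - rss_full / tss)
  model$early_parent <- early_parent
  model
}

#' Sum LOD scores over non-overlapping genomic windows
#'
#' The genome is tiled in non-overlapping windows of `window_bp`; the LOD
#' values of all supplied scans falling in a window are summed and reported
#' at the window center. Used to summarise many population x trait scans
#' in one genome-wide profile.
#'
#' @param scans a list of `qtl_scan` objects sharing a genome.
#' @param window_bp window size in bp (default 100 kb).
#' @return data.frame `chrom`, `center_bp`, `sum_lod`.
#' @export
window_lod_summary <- function(scans, window_bp = 1e5) {
  if (inherits(scans, "qtl_scan")) scans <- list(scans)
  all_pos <- do.call(rbind, lapply(scans, function(s)
    data.frame(chrom = s$chrom, pos_bp = s$pos_bp, lod = s$lod)))
  all_pos <- all_pos[!is.na(all_pos$pos_bp), ]
  win <- floor(all_pos$pos_bp / window_bp)
  agg <- stats::aggregate(lod ~ chrom + win, cbind(all_pos, win = win), sum)
  out <- data.frame(chrom = agg$chrom,
                    center_bp = (agg$win + 0.5) * window_bp,
                    sum_lod = agg$lod)
  out[order(out$chrom, out$center_bp), ]
}
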