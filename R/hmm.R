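#' Coverage and sample filtering of allele-count tables
#'
#' Removes sites on organellar contigs, zeroes out sites whose depth
#' deviates from the sample's mean depth by more than `sd_mult` standard
#' deviations (likely collapsed repeats; statistics are computed over all
#' of the sample's sites so that rare extreme pile-ups cannot mask
#' themselves), and rejects samples left with fewer than `min_sites`
#' informative (nonzero-depth) sites. When the depth SD is zero the
#' deviation rule is skipped with a warning, since the interval would
#' degenerate to a point.
#'
#' @param counts an `allele_counts` object.
#' @param organellar_contigs contig names to drop entirely.
#' @param sd_mult SD multiplier for the depth-outlier rule (default 5).
#' @param min_sites minimum informative sites per sample (default 7000).
#' @return Filtered `allele_counts`; rejected samples are recorded in
#'   attribute `"rejected"` (data.frame `sample`, `reason`).
#' @export
filter_counts <- function(counts, organellar_contigs = c("ChrM", "ChrC", "Mt", "Pt"),
                          sd_mult = 5, min_sites = 7000) {
  if (nrow(counts$sites) == 0) stop("empty allele-count table")
  keep_site <- !(counts$sites$chrom %in% organellar_contigs)
  counts$sites <- counts$sites[keep_site, , drop = FALSE]
  counts$ref <- counts$ref[, keep_site, drop = FALSE]
  counts$alt <- counts$alt[, keep_site, drop = FALSE]

  depth <- counts$ref + counts$alt
  sd_warned <- FALSE
  for (i in seq_along(counts$sample_ids)) {
    d <- depth[i, ]
    if (!any(d > 0)) next
    m <- mean(d); s <- stats::sd(d)
    if (is.na(s) || s == 0) {
      sd_warned <- TRUE
      next
    }
    bad <- d > 0 & (d < m - sd_mult * s | d > m + sd_mult * s)
    counts$ref[i, bad] <- 0L
    counts$alt[i, bad] <- 0L
    depth[i, bad] <- 0L
  }
  if (sd_warned)
    warning("zero depth variance for at least one sample; SD rule skipped")

  informative <- rowSums(depth > 0)
  ok <- informative >= min_sites
  rejected <- data.frame(sample = counts$sample_ids[!ok],
                         reason = sprintf("only %d informative sites (< %d)",
                                          informative[!ok], min_sites))
  counts$sample_ids <- counts$sample_ids[ok]
  counts$ref <- counts$ref[ok, , drop = FALSE]
  counts$alt <- counts$alt[ok, , drop = FALSE]
  attr(counts, "rejected") <- rejected
  counts
}

# log binomial emission matrix (n x 3) at one site: columns AA, AB, BB with
# ALT-read probabilities eps, 0.5, 1-eps. Zero-depth sites emit log(1) = 0
# for every state.
.emission_log <- function(alt, depth, eps) {
  cbind(stats::dbinom(alt, depth, eps, log = TRUE),
        stats::dbinom(alt, depth, 0.5, log = TRUE),
        stats::dbinom(alt, depth, 1 - eps, log = TRUE))
}

# Forward-backward + Viterbi for one chromosome, vectorised across samples.
# alt, depth: n x T; trans: list of 3x3 matrices per gap (length T-1).
# Returns list(states n x T, post list of three n x T matrices,
# loglik_fwd n, loglik_bwd n).
.hmm_chrom <- function(alt, depth, trans, eps, prior = c(0.25, 0.5, 0.25)) {
  n <- nrow(alt); Tn <- ncol(alt)
  emis <- vector("list", Tn)        # scaled emission probs (n x 3)
  emax <- matrix(0, n, Tn)          # the per-row log scale factors
  for (t in seq_len(Tn)) {
    le <- .emission_log(alt[, t], depth[, t], eps)
    mx <- le[, 1]
    mx <- pmax(mx, le[, 2]); mx <- pmax(mx, le[, 3])
    emis[[t]] <- exp(le - mx)
    emax[, t] <- mx
  }
  # forward with per-step normalisation
  alpha <- vector("list", Tn)
  logc <- matrix(0, n, Tn)
  a <- emis[[1]] * rep(prior, each = n)
  cs <- rowSums(a)
  alpha[[1]] <- a / cs; logc[, 1] <- log(cs)
  if (Tn > 1) for (t in 2:Tn) {
    a <- (alpha[[t - 1]] %*% trans[[t - 1]]) * emis[[t]]
    cs <- rowSums(a)
    alpha[[t]] <- a / cs; logc[, t] <- log(cs)
  }
  loglik_fwd <- rowSums(logc) + rowSums(emax)
  # backward
  beta <- matrix(1, n, 3)
  post <- vector("list", Tn)
  post[[Tn]] <- alpha[[Tn]] * beta
  post[[Tn]] <- post[[Tn]] / rowSums(post[[Tn]])
  logb <- numeric(n)
  if (Tn > 1) for (t in (Tn - 1):1) {
    b <- (beta * emis[[t + 1]]) %*% t(trans[[t]])
    cs <- rowSums(b)
    beta <- b / cs; logb <- logb + log(cs)
    g <- alpha[[t]] * beta
    post[[t]] <- g / rowSums(g)
  }
  # backward-route total likelihood: sum_s prior_s e_1s beta_1s * scales
  b1 <- rowSums(rep(prior, each = n) * emis[[1]] * beta)
  loglik_bwd <- log(b1) + logb + rowSums(emax)
  if (Tn == 1) loglik_bwd <- loglik_fwd
  # Viterbi in log space, ties broken toward staying in the same state
  ltr <- lapply(trans, log)
  delta <- log(rep(prior, each = n)) + log(emis[[1]]) + emax[, 1]
  dim(delta) <- c(n, 3)
  psi <- array(0L, c(Tn, n, 3))
  if (Tn > 1) for (t in 2:Tn) {
    lt <- ltr[[t - 1]]
    newd <- matrix(0, n, 3)
    for (j in 1:3) {
      cand <- delta + rep(lt[, j], each = n)
      m <- pmax(cand[, 1], cand[, 2], cand[, 3])
      pick <- max.col(cand, ties.method = "first")
      stay <- cand[, j] >= m
      pick[stay] <- j
      psi[t, , j] <- pick
      newd[, j] <- m
    }
    delta <- newd + log(emis[[t]]) + emax[, t]
  }
  states <- matrix(0L, n, Tn)
  states[, Tn] <- max.col(delta, ties.method = "first")
  if (Tn > 1) {
    for (t in Tn:2) {
      idx <- cbind(t, seq_len(n), states[, t])
      states[, t - 1] <- psi[idx]
    }
  }
  pAA <- vapply(post, function(p) p[, 1], numeric(n))
  pAB <- vapply(post, function(p) p[, 2], numeric(n))
  pBB <- vapply(post, function(p) p[, 3], numeric(n))
  if (n == 1) { pAA <- matrix(pAA, 1); pAB <- matrix(pAB, 1); pBB <- matrix(pBB, 1) }
  list(states = states, post = list(AA = pAA, AB = pAB, BB = pBB),
       loglik_fwd = loglik_fwd, loglik_bwd = loglik_bwd)
}

#' Reconstruct F2 genotypes from sparse allele counts
#'
#' Three-state (AA/AB/BB) hidden Markov model over the informative sites of
#' each chromosome. Emissions are binomial: an ALT count k out of depth n
#' has success probability `error_rate`, 0.5 or `1 - error_rate` under AA,
#' AB, BB; zero-depth sites emit uniformly. Transitions between adjacent
#' sites use the F2 two-locus genotype matrix at the Haldane recombination
#' fraction implied by the physical gap times the genome's cM/Mb. The state
#' sequence is decoded by Viterbi (ties favour staying, i.e. fewer
#' crossovers); per-site posteriors come from the forward-backward
#' algorithm. Sites deeper than `depth_cap` reads are proportionally
#' down-scaled as a guard against overdispersed pile-ups.
#'
#' @param counts an `allele_counts` object (after [filter_counts()]).
#' @param genome a `genome_spec`.
#' @param error_rate per-read error probability in `[0, 0.5)`.
#' @param depth_cap maximum depth used per site (default 50).
#' @return A `genotype_paths` object: list with `sites`, `sample_ids`,
#'   `states` (samples x sites, 1/2/3), `post` (list of AA/AB/BB posterior
#'   matrices), `loglik_fwd`, `loglik_bwd`, `genome`, `error_rate`.
#' @export
reconstruct <- function(counts, genome, error_rate = 0.01, depth_cap = 50) {
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must be in [0, 0.5)")
  stopifnot(inherits(genome, "genome_spec"))
  chroms <- unique(counts$sites$chrom)
  if (!all(chroms %in% genome$chromosomes$chrom))
    stop("allele-count contigs not in genome spec")
  n <- length(counts$sample_ids)
  Tn <- nrow(counts$sites)
  states <- matrix(0L, n, Tn)
  post <- list(AA = matrix(0, n, Tn), AB = matrix(0, n, Tn),
               BB = matrix(0, n, Tn))
  ll_f <- matrix(0, n, length(chroms)); ll_b <- ll_f
  for (ci in seq_along(chroms)) {
    sel <- which(counts$sites$chrom == chroms[ci])
    sel <- sel[order(counts$sites$pos[sel])]
    alt <- counts$alt[, sel, drop = FALSE]
    depth <- counts$ref[, sel, drop = FALSE] + alt
    over <- depth > depth_cap
    if (any(over)) {
      alt[over] <- as.integer(round(alt[over] * depth_cap / depth[over]))
      depth[over] <- as.integer(depth_cap)
    }
    gaps_cm <- diff(counts$sites$pos[sel]) / 1e6 * genome$cm_per_mb
    trans <- lapply(haldane_r(gaps_cm), f2_transition)
    res <- .hmm_chrom(alt, depth, trans, error_rate)
    states[, sel] <- res$states
    post$AA[, sel] <- res$post$AA
    post$AB[, sel] <- res$post$AB
    post$BB[, sel] <- res$post$BB
    ll_f[, ci] <- res$loglik_fwd; ll_b[, ci] <- res$loglik_bwd
  }
  structure(list(sites = counts$sites, sample_ids = counts$sample_ids,
                 states = states, post = post,
                 loglik_fwd = rowSums(ll_f), loglik_bwd = rowSums(ll_b),
                 genome = genome, error_rate = error_rate),
            class = "genotype_paths")
}

#' @export
print.genotype_paths <- function(x, ...) {
  cat(sprintf("genotype_paths: %d samples x %d sites on %d chromosomes\n",
              length(x$sample_ids), nrow(x$sites),
              length(unique(x$sites$chrom))))
  invisible(x)
}

#' Extract genotype segments from reconstructed paths
#'
#' Runs of constant Viterbi state become segments. Segment boundaries are
#' the midpoints of the bracketing informative-site intervals; terminal
#' segments extend to the chromosome ends. The per-segment confidence is
#' the mean posterior probability of the called state over the segment's
#' sites.
#'
#' @param paths a `genotype_paths` object.
#' @return data.frame `sample`, `chrom`, `start`, `end`, `state`,
#'   `n_sites`, `confidence`.
#' @export
path_segments <- function(paths) {
  st_names <- c("AA", "AB", "BB")
  out <- list()
  for (i in seq_along(paths$sample_ids)) {
    for (chrom in unique(paths$sites$chrom)) {
      sel <- which(paths$sites$chrom == chrom)
      pos <- paths$sites$pos[sel]
      s <- paths$states[i, sel]
      r <- rle(s)
      ends_idx <- cumsum(r$lengths)
      starts_idx <- c(1, utils::head(ends_idx, -1) + 1)
      L <- paths$genome$chromosomes$length_bp[
        paths$genome$chromosomes$chrom == chrom]
      # boundaries at midpoints between last site of one run and first of next
      bounds <- if (length(r$values) > 1)
        (pos[ends_idx[-length(ends_idx)]] + pos[starts_idx[-1]]) / 2
      else numeric(0)
      seg_start <- c(0, bounds)
      seg_end <- c(bounds, L)
      conf <- vapply(seq_along(r$values), function(k) {
        idx <- sel[starts_idx[k]:ends_idx[k]]
        mean(paths$post[[r$values[k]]][i, idx])
      }, 0)
      out[[length(out) + 1]] <- data.frame(
        sample = paths$sample_ids[i], chrom = chrom,
        start = seg_start, end = seg_end,
        state = st_names[r$values], n_sites = r$lengths, confidence = conf)
    }
  }
  do.call(rbind, out)
}

#' Call crossover events from reconstructed paths
#'
#' One event per Viterbi state change. The breakpoint is placed at the
#' midpoint of the bracketing informative-site interval; the event
#' confidence is the smaller of the two flanking segments' mean posterior
#' mass. Adjacent AA/BB segments (a collapsed double crossover) are counted
#' as a single state change but flagged non-canonical.
#'
#' @param paths a `genotype_paths` object.
#' @return data.frame `sample`, `chrom`, `left_bp`, `right_bp`, `midpoint`,
#'   `from`, `to`, `confidence`, `canonical`.
#' @export
call_crossovers <- function(paths) {
  st_names <- c("AA", "AB", "BB")
  out <- list()
  for (i in seq_along(paths$sample_ids)) {
    for (chrom in unique(paths$sites$chrom)) {
      sel <- which(paths$sites$chrom == chrom)
      pos <- paths$sites$pos[sel]
      s <- paths$states[i, sel]
      r <- rle(s)
      if (length(r$values) < 2) next
      ends_idx <- cumsum(r$lengths)
      starts_idx <- c(1, utils::head(ends_idx, -1) + 1)
      conf <- vapply(seq_along(r$values), function(k) {
        idx <- sel[starts_idx[k]:ends_idx[k]]
        mean(paths$post[[r$values[k]]][i, idx])
      }, 0)
      k <- seq_len(length(r$values) - 1)
      out[[length(out) + 1]] <- data.frame(
        sample = paths$sample_ids[i], chrom = chrom,
        left_bp = pos[ends_idx[k]], right_bp = pos[starts_idx[k + 1]],
        midpoint = (pos[ends_idx[k]] + pos[starts_idx[k + 1]]) / 2,
        from = st_names[r$values[k]], to = st_names[r$values[k + 1]],
        confidence = pmin(conf[k], conf[k + 1]),
        canonical = abs(r$values[k + 1] - r$values[k]) == 1)
    }
  }
  if (length(out) == 0)
    return(data.frame(sample = character(), chrom = character(),
                      left_bp = numeric(), right_bp = numeric(),
                      midpoint = numeric(), from = character(),
                      to = character(), confidence = numeric(),
                      canonical = logical()))
  do.call(rbind, out)
}

#' Site-level genotype accuracy against simulated truth
#'
#' @param paths a `genotype_paths` object.
#' @param truth the `f2_truth` the counts were simulated from (samples
#'   matched by id).
#' @return Fraction of (sample, site) pairs where the Viterbi state equals
#'   the true state.
#' @export
genotype_accuracy <- function(paths, truth) {
  ids <- vapply(truth, `[[`, "", "id")
  keep <- match(paths$sample_ids, ids)
  if (anyNA(keep)) stop("samples missing from truth")
  g <- true_genotypes(truth[keep], paths$sites)
  mean(paths$states == g)
}
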