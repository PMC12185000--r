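# Shared fixtures and independent oracles, all built in code.

# small single-chromosome genome for focused tests
tiny_genome <- function(length_mb = 30, cm_per_mb = 4) {
  genome_spec(data.frame(chrom = "Chr1", length_bp = length_mb * 1e6),
              cm_per_mb = cm_per_mb)
}

# hand-build an allele_counts object (one or more samples, one chromosome)
manual_counts <- function(alt, depth, pos, chrom = "Chr1",
                          ids = sprintf("S%d", seq_len(nrow(alt)))) {
  alt <- rbind(alt); depth <- rbind(depth)
  structure(list(sites = data.frame(chrom = chrom, pos = pos),
                 ref = depth - alt, alt = alt, sample_ids = ids),
            class = "allele_counts")
}

# Independent brute-force HMM oracle: enumerates every state path.
# The F2 transition probabilities and Haldane map function are written out
# from first principles rather than calling the package.
oracle_hmm <- function(alt, depth, pos_bp, cm_per_mb, eps,
                       prior = c(0.25, 0.5, 0.25)) {
  Tn <- length(alt)
  p_alt <- c(eps, 0.5, 1 - eps)
  trans_at <- function(d_cm) {
    r <- 0.5 * (1 - exp(-2 * d_cm / 100))
    matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
             r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
             r^2, 2 * r * (1 - r), (1 - r)^2), 3, byrow = TRUE)
  }
  trans <- lapply(diff(pos_bp) / 1e6 * cm_per_mb, trans_at)
  paths <- as.matrix(expand.grid(rep(list(1:3), Tn)))
  ll <- apply(paths, 1, function(s) {
    lp <- log(prior[s[1]]) + sum(dbinom(alt, depth, p_alt[s], log = TRUE))
    if (Tn > 1)
      for (t in 2:Tn) lp <- lp + log(trans[[t - 1]][s[t - 1], s[t]])
    lp
  })
  mx <- max(ll)
  list(loglik = log(sum(exp(ll - mx))) + mx,
       viterbi = unname(paths[which.max(ll), ]),
       viterbi_loglik = mx)
}

# direct least-squares LOD oracle on given predictors
oracle_lod <- function(y, xa, xd) {
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  rss1 <- sum(resid(lm(y ~ xa + xd))^2)
  rss1 <- max(rss1, 1e-12 * max(tss, 1))
  (n / 2) * log10(tss / rss1)
}

# adjusted Rand index for cluster-recovery checks
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# build a mapping-ready cross with a planted additive QTL
planted_cross <- function(n_ind, chrom, pos_bp, a, residual_sd = 1,
                          genome = default_genome(), seed = 1) {
  truth <- simulate_f2(genome, n_ind, seed = seed)
  qs <- qtl_spec(chrom = chrom, pos_bp = pos_bp, a = a,
                 residual_sd = residual_sd)
  ph <- simulate_phenotypes(truth, qs, seed = seed + 1)
  cr <- cross_from_truth(truth, genome,
                         pheno = data.frame(id = ph$id, DTF = ph$phenotype))
  estimate_genetic_map(cr)
}
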