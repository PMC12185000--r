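#' Construct an F2 cross object
#'
#' The central container of the mapping stages: an individuals x markers
#' genotype matrix (1 = AA, 2 = AB, 3 = BB, NA = missing), marker metadata
#' with physical and (optionally) genetic positions, phenotypes, and a QC
#' log that records every removal with its stage and reason.
#'
#' @param geno integer matrix (individuals x markers) with values 1/2/3/NA;
#'   rownames are individual ids.
#' @param markers data.frame with `chrom`, `pos_bp` and optionally `cm`;
#'   marker ids default to `chrom_pos`.
#' @param genome optional `genome_spec`.
#' @param pheno optional data.frame with an `id` column and trait columns.
#' @return An object of class `f2cross`.
#' @export
make_cross <- function(geno, markers, genome = NULL, pheno = NULL) {
  stopifnot(is.matrix(geno), nrow(markers) == ncol(geno))
  if (is.null(markers$id))
    markers$id <- sprintf("%s_%d", markers$chrom, round(markers$pos_bp))
  if (is.null(markers$cm)) markers$cm <- NA_real_
  for (chrom in unique(markers$chrom)) {
    p <- markers$pos_bp[markers$chrom == chrom]
    if (!anyNA(p) && is.unsorted(p))
      stop("marker physical positions must be sorted within chromosome")
  }
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("ind_%04d", seq_len(nrow(geno)))
  colnames(geno) <- markers$id
  if (!is.null(pheno)) {
    stopifnot("id" %in% names(pheno))
    pheno <- pheno[match(rownames(geno), pheno$id), , drop = FALSE]
  }
  structure(list(geno = geno,
                 markers = markers[, c("id", "chrom", "pos_bp", "cm")],
                 pheno = pheno, genome = genome,
                 qc_log = data.frame(stage = character(), item = character(),
                                     reason = character())),
            class = "f2cross")
}

#' @export
print.f2cross <- function(x, ...) {
  cat(sprintf("f2cross: %d individuals x %d markers on %d chromosomes; %d phenotype(s); %d QC removals logged\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$markers$chrom)),
              if (is.null(x$pheno)) 0 else ncol(x$pheno) - 1, nrow(x$qc_log)))
  invisible(x)
}

#' Attach phenotypes to a cross
#' @param cross an `f2cross`.
#' @param pheno data.frame with `id` and trait columns.
#' @return The cross with phenotypes matched by individual id.
#' @export
set_pheno <- function(cross, pheno) {
  stopifnot("id" %in% names(pheno))
  cross$pheno <- pheno[match(rownames(cross$geno), pheno$id), , drop = FALSE]
  cross
}

.log_qc <- function(cross, stage, items, reason) {
  if (length(items) == 0) return(cross)
  cross$qc_log <- rbind(cross$qc_log,
                        data.frame(stage = stage, item = items, reason = reason))
  cross
}

#' Build population markers from reconstructed genotype paths
#'
#' The union of all crossover breakpoints across individuals partitions
#' each chromosome into intervals; every interval becomes one marker placed
#' at its midpoint. An individual's genotype at a marker is the state of
#' its segment covering the marker, set to missing when the segment's
#' posterior confidence falls below `conf_threshold`.
#'
#' @param paths a `genotype_paths` object (>= 2 individuals).
#' @param pheno optional phenotype data.frame with `id`.
#' @param conf_threshold minimum flanking-segment posterior (default 0.95).
#' @return An `f2cross`.
#' @export
build_markers <- function(paths, pheno = NULL, conf_threshold = 0.95) {
  if (length(paths$sample_ids) < 2) stop("need at least 2 individuals")
  segs <- path_segments(paths)
  cos <- call_crossovers(paths)
  if (nrow(cos) == 0)
    warning("no crossovers in the population; one marker per chromosome")
  chroms <- paths$genome$chromosomes
  states <- c(AA = 1L, AB = 2L, BB = 3L)
  marker_list <- list(); geno_list <- list()
  for (i in seq_len(nrow(chroms))) {
    chrom <- chroms$chrom[i]; L <- chroms$length_bp[i]
    bp <- sort(unique(cos$midpoint[cos$chrom == chrom]))
    cuts <- c(0, bp, L)
    mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
    marker_list[[i]] <- data.frame(chrom = chrom, pos_bp = mids)
    g <- matrix(NA_integer_, length(paths$sample_ids), length(mids))
    for (s in seq_along(paths$sample_ids)) {
      ss <- segs[segs$sample == paths$sample_ids[s] & segs$chrom == chrom, ]
      idx <- findInterval(mids, ss$start)
      idx[idx < 1] <- 1L
      gi <- states[ss$state[idx]]
      gi[ss$confidence[idx] < conf_threshold] <- NA_integer_
      g[s, ] <- gi
    }
    geno_list[[i]] <- g
  }
  geno <- do.call(cbind, geno_list)
  rownames(geno) <- paths$sample_ids
  make_cross(geno, do.call(rbind, marker_list), genome = paths$genome,
             pheno = pheno)
}

# genome-wide crossover count per individual from the genotype matrix:
# adjacent non-missing state changes, AA<->BB weighted as two events.
.count_crossovers <- function(cross) {
  counts <- integer(nrow(cross$geno))
  for (chrom in unique(cross$markers$chrom)) {
    g <- cross$geno[, cross$markers$chrom == chrom, drop = FALSE]
    for (i in seq_len(nrow(g))) {
      v <- g[i, !is.na(g[i, ])]
      if (length(v) > 1) counts[i] <- counts[i] + sum(abs(diff(v)))
    }
  }
  counts
}

#' Individual-level quality control
#'
#' Applies, in order: removal of individuals with few called markers
#' (below `min_marker_frac` of the population median called-marker count);
#' removal of one member of every pair with genotype identity of at least
#' `similarity_cutoff` over shared non-missing markers (the member with
#' fewer called markers is dropped; ties drop the later id); and removal of
#' individuals with more than `max_crossovers` genome-wide crossovers.
#'
#' @param cross an `f2cross`.
#' @param min_marker_frac fraction of the median called-marker count below
#'   which an individual is dropped (default 0.5).
#' @param similarity_cutoff pairwise genotype-identity cutoff (default 0.9).
#' @param max_crossovers maximum genome-wide crossover count (default 25).
#' @return The cross with individuals removed and the QC log extended.
#' @export
qc_individuals <- function(cross, min_marker_frac = 0.5,
                           similarity_cutoff = 0.9, max_crossovers = 25) {
  called <- rowSums(!is.na(cross$geno))
  thr <- min_marker_frac * stats::median(called)
  drop1 <- rownames(cross$geno)[called < thr]
  cross <- .log_qc(cross, "low_marker_count", drop1,
                   sprintf("called markers below %.0f", thr))
  keep <- !(rownames(cross$geno) %in% drop1)
  cross$geno <- cross$geno[keep, , drop = FALSE]
  if (!is.null(cross$pheno)) cross$pheno <- cross$pheno[keep, , drop = FALSE]

  # pairwise identity over shared non-missing markers
  g <- cross$geno
  n <- nrow(g)
  called <- rowSums(!is.na(g))
  alive <- rep(TRUE, n)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      if (!alive[i]) next
      for (j in (i + 1):n) {
        if (!alive[j]) next
        shared <- !is.na(g[i, ]) & !is.na(g[j, ])
        if (!any(shared)) next
        sim <- mean(g[i, shared] == g[j, shared])
        if (sim >= similarity_cutoff) {
          victim <- if (called[i] < called[j]) i
          else if (called[j] < called[i]) j
          else max(i, j)                      # tie: later sample id
          alive[victim] <- FALSE
          cross <- .log_qc(cross, "similar_genotype", rownames(g)[victim],
                           sprintf("identity %.3f with %s", sim,
                                   rownames(g)[c(i, j)[c(i, j) != victim]]))
        }
      }
    }
  }
  cross$geno <- cross$geno[alive, , drop = FALSE]
  if (!is.null(cross$pheno)) cross$pheno <- cross$pheno[alive, , drop = FALSE]

  nco <- .count_crossovers(cross)
  dropc <- rownames(cross$geno)[nco > max_crossovers]
  cross <- .log_qc(cross, "excess_crossovers", dropc,
                   sprintf("%d crossovers (> %d)", nco[nco > max_crossovers],
                           max_crossovers))
  keep <- !(rownames(cross$geno) %in% dropc)
  cross$geno <- cross$geno[keep, , drop = FALSE]
  if (!is.null(cross$pheno)) cross$pheno <- cross$pheno[keep, , drop = FALSE]
  if (nrow(cross$geno) == 0) stop("individual QC removed every individual")
  cross
}

#' Chi-square test for segregation distortion against 1:2:1
#'
#' Goodness-of-fit of observed AA/AB/BB counts to the Mendelian F2
#' expectation, without continuity correction, on 2 degrees of freedom.
#'
#' @param n_aa,n_ab,n_bb genotype counts.
#' @return list with `chisq`, `p`, `expected`.
#' @export
distortion_test <- function(n_aa, n_ab, n_bb) {
  obs <- c(n_aa, n_ab, n_bb)
  n <- sum(obs)
  expd <- n * c(0.25, 0.5, 0.25)
  chisq <- sum((obs - expd)^2 / expd)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 2, lower.tail = FALSE),
       expected = expd)
}

#' Marker-level quality control
#'
#' Removes markers missing in more than `max_missing_frac` of individuals,
#' then markers whose genotype counts (over non-missing individuals) fail
#' the 1:2:1 goodness-of-fit at `p < distortion_p`.
#'
#' @param cross an `f2cross` (individuals already QC'd).
#' @param max_missing_frac maximum missing fraction (default 0.1).
#' @param distortion_p segregation-distortion p-value cutoff (default 1e-7).
#' @return The cross with markers removed and the QC log extended.
#' @export
qc_markers <- function(cross, max_missing_frac = 0.1, distortion_p = 1e-7) {
  miss <- colMeans(is.na(cross$geno))
  drop_miss <- cross$markers$id[miss > max_missing_frac]
  cross <- .log_qc(cross, "marker_missing", drop_miss,
                   sprintf("missing fraction %.2f (> %.2f)",
                           miss[miss > max_missing_frac], max_missing_frac))
  keep <- !(cross$markers$id %in% drop_miss)
  cross$geno <- cross$geno[, keep, drop = FALSE]
  cross$markers <- cross$markers[keep, , drop = FALSE]

  pvals <- apply(cross$geno, 2, function(g) {
    tab <- tabulate(g[!is.na(g)], nbins = 3)
    distortion_test(tab[1], tab[2], tab[3])$p
  })
  drop_dist <- cross$markers$id[pvals < distortion_p]
  cross <- .log_qc(cross, "segregation_distortion", drop_dist,
                   sprintf("1:2:1 chi-square p = %.3g", pvals[pvals < distortion_p]))
  keep <- !(cross$markers$id %in% drop_dist)
  cross$geno <- cross$geno[, keep, drop = FALSE]
  cross$markers <- cross$markers[keep, , drop = FALSE]
  cross
}

# maximum-likelihood recombination fraction between two adjacent markers
# from the F2 two-locus table; boundary case r = 0 handled directly.
.estimate_rf <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) return(0)
  tab <- table(factor(g1[ok], 1:3), factor(g2[ok], 1:3))
  if (sum(tab) == sum(diag(tab))) return(0)   # no recombinants observed
  nll <- function(r) {
    P <- f2_transition(r)
    -sum(tab * log(pmax(P, 1e-300)))
  }
  stats::optimize(nll, c(1e-6, 0.49))$minimum
}

#' Estimate a genetic map from the genotype matrix
#'
#' Adjacent-marker recombination fractions are estimated by maximum
#' likelihood over the F2 two-locus genotype probabilities and converted to
#' centimorgan with the inverse Haldane function (capped at r = 0.49);
#' positions are cumulative within each chromosome starting at 0.
#'
#' @param cross an `f2cross` with markers sorted by physical position.
#' @return The cross with `markers$cm` filled in.
#' @export
estimate_genetic_map <- function(cross) {
  cm <- numeric(nrow(cross$markers))
  for (chrom in unique(cross$markers$chrom)) {
    sel <- which(cross$markers$chrom == chrom)
    if (is.unsorted(cross$markers$pos_bp[sel]))
      stop("marker physical positions must be sorted within chromosome")
    pos <- 0
    cm[sel[1]] <- 0
    if (length(sel) > 1) {
      for (k in 2:length(sel)) {
        r <- .estimate_rf(cross$geno[, sel[k - 1]], cross$geno[, sel[k]])
        pos <- pos + haldane_cm(r)
        cm[sel[k]] <- pos
      }
    }
  }
  cross$markers$cm <- cm
  cross
}

#' Write a cross to a rotated-CSV file
#'
#' The "csvr" dialect: one row per phenotype (name in the first column,
#' chromosome and position cells empty), then one row per marker (id,
#' chromosome, position in cM, then genotype codes A/H/B with `-` for
#' missing); columns beyond the third are the individuals.
#'
#' @param cross an `f2cross` with at least one phenotype column and an
#'   estimated genetic map.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_cross <- function(cross, path) {
  if (is.null(cross$pheno) || ncol(cross$pheno) < 2)
    stop("cross has no phenotypes; csvr needs at least one phenotype row")
  if (anyNA(cross$markers$cm))
    stop("genetic map missing; run estimate_genetic_map() first")
  traits <- setdiff(names(cross$pheno), "id")
  codes <- c("A", "H", "B")
  geno_chr <- matrix(codes[cross$geno], nrow(cross$geno), ncol(cross$geno))
  geno_chr[is.na(cross$geno)] <- "-"
  ph_rows <- t(vapply(traits, function(tr)
    c(tr, "", "", as.character(cross$pheno[[tr]])),
    character(3 + nrow(cross$geno))))
  mk_rows <- cbind(cross$markers$id, cross$markers$chrom,
                   sprintf("%.6f", cross$markers$cm), t(geno_chr))
  utils::write.table(rbind(ph_rows, mk_rows), path, sep = ",",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a cross from a rotated-CSV file
#'
#' Inverse of [write_cross()]. Physical positions are recovered from marker
#' ids of the form `chrom_pos`; otherwise they are set to NA.
#'
#' @param path CSV path.
#' @return An `f2cross` (without a genome spec).
#' @export
read_cross <- function(path) {
  raw <- utils::read.table(path, sep = ",", header = FALSE,
                           colClasses = "character")
  is_marker <- raw[[2]] != ""
  if (!any(!is_marker)) stop("no phenotype rows found")
  ph <- raw[!is_marker, , drop = FALSE]
  mk <- raw[is_marker, , drop = FALSE]
  n_ind <- ncol(raw) - 3
  pheno <- data.frame(id = sprintf("ind_%04d", seq_len(n_ind)))
  for (i in seq_len(nrow(ph)))
    pheno[[ph[i, 1]]] <- suppressWarnings(as.numeric(ph[i, -(1:3)]))
  code_map <- c(A = 1L, H = 2L, B = 3L)
  geno <- t(apply(as.matrix(mk[, -(1:3), drop = FALSE]), 1,
                  function(r) unname(code_map[r])))
  geno <- t(geno)   # individuals x markers
  pos_bp <- suppressWarnings(as.numeric(sub("^.*_", "", mk[[1]])))
  markers <- data.frame(id = mk[[1]], chrom = mk[[2]],
                        pos_bp = pos_bp, cm = as.numeric(mk[[3]]))
  rownames(geno) <- pheno$id
  out <- make_cross(geno, markers, pheno = pheno)
  out
}
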