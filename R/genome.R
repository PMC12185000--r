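#' Define the physical/genetic coordinate frame of a genome
#'
#' A genome specification holds the chromosome sizes, the genetic-to-physical
#' scale and any regions excluded from marker generation (centromeres,
#' telomeres, transposable-element annotations). All pipeline stages that need
#' coordinates take one of these objects.
#'
#' @param chromosomes data.frame with columns `chrom` (character) and
#'   `length_bp` (positive integer-ish). Order defines genome order.
#' @param cm_per_mb genetic-to-physical scale in centimorgan per megabase;
#'   a single positive number applied genome-wide.
#' @param excluded_regions optional data.frame with columns `chrom`, `start`
#'   (0-based), `end` (exclusive) and `class` (one of `"centromere"`,
#'   `"telomere"`, `"TE"`); intervals must lie within their chromosome.
#'
#' @return An object of class `genome_spec`: a list with elements
#'   `chromosomes`, `cm_per_mb`, `excluded_regions`.
#' @export
#' @examples
#' g <- genome_spec(data.frame(chrom = "Chr1", length_bp = 30e6), cm_per_mb = 4)
#' genome_length_cm(g)
genome_spec <- function(chromosomes, cm_per_mb = 4,
                        excluded_regions = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length_bp") %in% names(chromosomes)))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  if (anyDuplicated(chromosomes$chrom))
    stop("duplicated chromosome names")
  if (any(chromosomes$length_bp <= 0))
    stop("chromosome lengths must be positive")
  if (!is.numeric(cm_per_mb) || length(cm_per_mb) != 1 || cm_per_mb <= 0)
    stop("cm_per_mb must be a single positive number")
  if (is.null(excluded_regions)) {
    excluded_regions <- data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), class = character())
  } else {
    stopifnot(all(c("chrom", "start", "end") %in% names(excluded_regions)))
    if (is.null(excluded_regions$class)) excluded_regions$class <- "region"
    m <- match(excluded_regions$chrom, chromosomes$chrom)
    if (anyNA(m)) stop("excluded region on unknown chromosome")
    if (any(excluded_regions$start < 0) ||
        any(excluded_regions$end > chromosomes$length_bp[m]) ||
        any(excluded_regions$end <= excluded_regions$start))
      stop("excluded regions must be non-empty intervals within their chromosome")
  }
  structure(list(chromosomes = chromosomes, cm_per_mb = cm_per_mb,
                 excluded_regions = excluded_regions),
            class = "genome_spec")
}

#' Default five-chromosome genome
#'
#' An Arabidopsis-like genome of five chromosomes (30, 20, 23, 19, 27 Mb)
#' at 4 cM/Mb, with a 2-Mb centromeric exclusion zone in the middle of each
#' chromosome and 100-kb telomeric zones at the ends.
#'
#' @param cm_per_mb genetic-to-physical scale (default 4).
#' @param with_exclusions include centromere/telomere exclusion regions.
#' @return A `genome_spec`.
#' @export
default_genome <- function(cm_per_mb = 4, with_exclusions = TRUE) {
  len <- c(30, 20, 23, 19, 27) * 1e6
  chr <- paste0("Chr", 1:5)
  excl <- NULL
  if (with_exclusions) {
    mid <- len / 2
    excl <- rbind(
      data.frame(chrom = chr, start = mid - 1e6, end = mid + 1e6,
                 class = "centromere"),
      data.frame(chrom = chr, start = 0, end = 1e5, class = "telomere"),
      data.frame(chrom = chr, start = len - 1e5, end = len, class = "telomere")
    )
  }
  genome_spec(data.frame(chrom = chr, length_bp = len), cm_per_mb, excl)
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome_spec: %d chromosomes, %.1f Mb total, %.1f cM/Mb, %d excluded regions\n",
              nrow(x$chromosomes), sum(x$chromosomes$length_bp) / 1e6,
              x$cm_per_mb, nrow(x$excluded_regions)))
  invisible(x)
}

#' Total genetic length in centimorgan
#' @param genome a `genome_spec`.
#' @return Named numeric vector of per-chromosome lengths in cM.
#' @export
genome_length_cm <- function(genome) {
  stats::setNames(genome$chromosomes$length_bp / 1e6 * genome$cm_per_mb,
                  genome$chromosomes$chrom)
}

#' Haldane map functions
#'
#' `haldane_r` converts a genetic distance in cM to a recombination fraction
#' under no interference; `haldane_cm` is its inverse (capped at r = 0.49 to
#' stay finite).
#'
#' @param d_cm genetic distance in centimorgan.
#' @param r recombination fraction in `[0, 0.5)`.
#' @return Numeric vector.
#' @export
haldane_r <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))

#' @rdname haldane_r
#' @export
haldane_cm <- function(r) {
  r <- pmin(r, 0.49)
  -50 * log(1 - 2 * r)
}

# F2 genotype transition matrix between two loci at recombination fraction r.
# Rows/cols ordered AA, AB, BB. Derived from independent transmission through
# the two gametes of the selfed F1.
f2_transition <- function(r) {
  matrix(c((1 - r)^2,       2 * r * (1 - r),       r^2,
           r * (1 - r),     (1 - r)^2 + r^2,       r * (1 - r),
           r^2,             2 * r * (1 - r),       (1 - r)^2),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("AA", "AB", "BB"), c("AA", "AB", "BB")))
}

# F2 prior at any locus.
f2_prior <- c(AA = 0.25, AB = 0.5, BB = 0.25)

# map a per-seed integer stream: derive sub-seeds reproducibly from one seed
# while staying within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483647)
}
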