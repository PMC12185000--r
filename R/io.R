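#' Write parental variants to VCF
#'
#' Writes a VCF v4.2 with the five quality annotations (QD, FS, MQ,
#' MQRankSum, ReadPosRankSum) in INFO. Output is bgzip-style gzipped, as
#' written by [vcfR::write.vcf()]; use a `.vcf.gz` path.
#'
#' @param variants a `parental_variants` data.frame.
#' @param path output path (`.vcf.gz`).
#' @param genome optional `genome_spec` used to emit contig header lines.
#' @return The path, invisibly.
#' @export
write_parent_vcf <- function(variants, path, genome = NULL) {
  anns <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")
  meta <- c("##fileformat=VCFv4.2",
            sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                    anns, anns))
  if (!is.null(genome))
    meta <- c(meta, sprintf("##contig=<ID=%s,length=%d>",
                            genome$chromosomes$chrom,
                            as.integer(genome$chromosomes$length_bp)))
  info <- apply(vapply(anns, function(a) {
    ifelse(is.na(variants[[a]]), NA_character_,
           sprintf("%s=%.4f", a, variants[[a]]))
  }, character(nrow(variants))), 1, function(r)
    paste(r[!is.na(r)], collapse = ";"))
  fix <- cbind(CHROM = as.character(variants$chrom),
               POS = as.character(variants$pos),
               ID = rep(".", nrow(variants)),
               REF = variants$ref, ALT = variants$alt,
               QUAL = rep(".", nrow(variants)),
               FILTER = rep(".", nrow(variants)),
               INFO = info)
  v <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                    meta = meta, fix = fix,
                    gt = matrix(character(0), nrow = 0, ncol = 0))
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read parental variants from VCF
#'
#' Reads a VCF (plain or gzipped) and returns a `parental_variants`
#' data.frame with parsed numeric annotations. Records that are not
#' biallelic SNPs are kept but can be removed with
#' [select_biallelic_and_alt_parent()].
#'
#' @param path VCF path.
#' @param source_parent label stored on each record.
#' @return A `parental_variants` data.frame.
#' @export
read_parent_vcf <- function(path, source_parent = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  out <- data.frame(chrom = fx[, "CHROM"],
                    pos = as.numeric(fx[, "POS"]),
                    ref = fx[, "REF"], alt = fx[, "ALT"],
                    source_parent = source_parent)
  for (a in c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum"))
    out[[a]] <- suppressWarnings(
      as.numeric(vcfR::extract.info(v, element = a)))
  out$filter_status <- "pass"
  class(out) <- c("parental_variants", "data.frame")
  out
}

#' Write and read exclusion regions as BED
#'
#' BED intervals are 0-based half-open; the region class (centromere,
#' telomere, TE) is carried in the name column.
#'
#' @param regions data.frame with `chrom`, `start` (0-based), `end`, `class`.
#' @param path BED path.
#' @return `write_exclusion_bed` returns the path invisibly;
#'   `read_exclusion_bed` returns the regions data.frame.
#' @export
write_exclusion_bed <- function(regions, path) {
  utils::write.table(
    data.frame(regions$chrom, format(regions$start, scientific = FALSE, trim = TRUE),
               format(regions$end, scientific = FALSE, trim = TRUE),
               if (is.null(regions$class)) "region" else regions$class),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_exclusion_bed
#' @export
read_exclusion_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "class")[1:4],
                           fill = TRUE, stringsAsFactors = FALSE)
  if (!is.character(bed$class) || all(is.na(bed$class))) bed$class <- "region"
  bed[, c("chrom", "start", "end", "class")]
}

#' Write per-sample allele-count tables
#'
#' One tab-separated file per sample with header
#' `CONTIG POSITION REF_COUNT ALT_COUNT` (the allelic-counts convention).
#'
#' @param counts an `allele_counts` object.
#' @param dir output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_allele_counts <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(counts$sample_ids, ".counts.tsv"))
  for (i in seq_along(counts$sample_ids)) {
    utils::write.table(
      data.frame(CONTIG = counts$sites$chrom,
                 POSITION = format(counts$sites$pos, scientific = FALSE, trim = TRUE),
                 REF_COUNT = counts$ref[i, ], ALT_COUNT = counts$alt[i, ]),
      paths[i], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Read per-sample allele-count tables
#'
#' Reads the files written by [write_allele_counts()] (a header line is
#' tolerated and detected). All samples must cover the same site set; sites
#' are sorted by (chromosome, position).
#'
#' @param paths character vector of per-sample TSV paths.
#' @param sample_ids sample names; default is the file basename without the
#'   `.counts.tsv` suffix.
#' @return An `allele_counts` object.
#' @export
read_allele_counts <- function(paths,
                               sample_ids = sub("\\.counts\\.tsv$", "",
                                                basename(paths))) {
  tabs <- lapply(paths, function(p) {
    first <- readLines(p, n = 1)
    has_header <- grepl("CONTIG", first, fixed = TRUE)
    tb <- utils::read.table(p, sep = "\t", header = has_header,
                            stringsAsFactors = FALSE)
    names(tb) <- c("CONTIG", "POSITION", "REF_COUNT", "ALT_COUNT")
    tb[order(tb$CONTIG, tb$POSITION), ]
  })
  key <- paste(tabs[[1]]$CONTIG, tabs[[1]]$POSITION)
  for (tb in tabs[-1])
    if (!identical(paste(tb$CONTIG, tb$POSITION), key))
      stop("allele-count files do not share one site set")
  structure(list(sites = data.frame(chrom = tabs[[1]]$CONTIG,
                                    pos = tabs[[1]]$POSITION),
                 ref = do.call(rbind, lapply(tabs, function(tb) tb$REF_COUNT)),
                 alt = do.call(rbind, lapply(tabs, function(tb) tb$ALT_COUNT)),
                 sample_ids = sample_ids),
            class = "allele_counts")
}

#' Write the simulation ground truth as JSON
#'
#' Stores segments, crossovers and (optionally) the planted QTL so that
#' downstream recovery can be scored outside R.
#'
#' @param truth an `f2_truth` object.
#' @param path output JSON path.
#' @param qtl optional `qtl_spec`.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(truth, path, qtl = NULL) {
  payload <- list(
    individuals = lapply(truth, function(ind)
      list(id = ind$id, segments = ind$segments, crossovers = ind$crossovers)))
  if (!is.null(qtl))
    payload$qtl <- list(loci = qtl$loci, residual_sd = qtl$residual_sd,
                        line_sd = qtl$line_sd, baseline = qtl$baseline)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a phenotype CSV with end-of-experiment censoring
#'
#' Days-to-flowering columns are censored with [censor_dtf()] on export
#' (values above 125 become 130).
#'
#' @param pheno data.frame of phenotypes.
#' @param path output CSV path.
#' @param dtf_cols names of columns to censor (default `"DTF"` when present).
#' @return The path, invisibly.
#' @export
write_pheno_csv <- function(pheno, path,
                            dtf_cols = intersect("DTF", names(pheno))) {
  for (cl in dtf_cols) pheno[[cl]] <- censor_dtf(pheno[[cl]])
  utils::write.csv(pheno, path, row.names = FALSE)
  invisible(path)
}

#' Run the synthetic-data generator from a YAML configuration
#'
#' The YAML file holds a `simulate:` block with `seed`, `genome`
#' (`chromosomes:` name-to-length map in bp, `cm_per_mb`), `n_variants`,
#' `n_individuals`, `coverage`, `error_rate` and an optional `qtl:` list
#' (`chrom`, `pos_bp`, `a`, `d`) plus `residual_sd`/`baseline`. Returns all
#' generated inputs with their ground truth.
#'
#' @param path YAML config path.
#' @return list with `genome`, `variants`, `truth`, `counts`, `pheno`,
#'   `qtl`.
#' @export
simulate_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)$simulate
  if (is.null(cfg)) stop("config lacks a 'simulate:' block")
  gcfg <- cfg$genome
  genome <- if (is.null(gcfg)) default_genome() else
    genome_spec(data.frame(chrom = names(gcfg$chromosomes),
                           length_bp = as.numeric(unlist(gcfg$chromosomes))),
                cm_per_mb = if (is.null(gcfg$cm_per_mb)) 4 else gcfg$cm_per_mb)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  variants <- simulate_parents(genome,
                               n_variants = if (is.null(cfg$n_variants)) 70000 else cfg$n_variants,
                               outlier_fraction = if (is.null(cfg$outlier_fraction)) 0.2 else cfg$outlier_fraction,
                               seed = derive_seed(seed, 1))
  truth <- simulate_f2(genome,
                       n_individuals = if (is.null(cfg$n_individuals)) 100 else cfg$n_individuals,
                       seed = derive_seed(seed, 2))
  counts <- simulate_allele_counts(truth, variants,
                                   mean_coverage = if (is.null(cfg$coverage)) 0.2 else cfg$coverage,
                                   error_rate = if (is.null(cfg$error_rate)) 0.01 else cfg$error_rate,
                                   seed = derive_seed(seed, 3))
  qtl <- NULL; pheno <- NULL
  if (!is.null(cfg$qtl)) {
    qtl <- qtl_spec(chrom = vapply(cfg$qtl, `[[`, "", "chrom"),
                    pos_bp = vapply(cfg$qtl, function(q) as.numeric(q$pos_bp), 0),
                    a = vapply(cfg$qtl, function(q) as.numeric(q$a), 0),
                    d = vapply(cfg$qtl, function(q)
                      if (is.null(q$d)) 0 else as.numeric(q$d), 0),
                    residual_sd = if (is.null(cfg$residual_sd)) 1 else cfg$residual_sd,
                    baseline = if (is.null(cfg$baseline)) 30 else cfg$baseline)
    pheno <- simulate_phenotypes(truth, qtl, seed = derive_seed(seed, 4))
  }
  list(genome = genome, variants = variants, truth = truth, counts = counts,
       pheno = pheno, qtl = qtl)
}
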