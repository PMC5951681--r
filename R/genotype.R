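#' Construct a genotype matrix object
#'
#' Container for biallelic SNP calls coded as alternate-allele counts
#' (0/1/2, `NA` = missing), with locus positions and sample-to-site
#' assignments. Loci are sorted by (chromosome, position) and must be unique;
#' sample ids must be unique.
#'
#' @param calls integer matrix, samples x loci, values in \{0,1,2,NA\}.
#' @param loci data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param samples data.frame with columns `sample_id`, `site_id`.
#' @return a `genotype_matrix` object.
#' @export
genotype_matrix <- function(calls, loci, samples) {
  calls <- as.matrix(calls)
  stopifnot(nrow(calls) == nrow(samples), ncol(calls) == nrow(loci))
  bad <- !(is.na(calls) | calls %in% c(0, 1, 2))
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or missing")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  if (anyDuplicated(loci[, c("chrom", "pos")])) {
    stop("duplicate locus positions")
  }
  rownames(calls) <- samples$sample_id
  rownames(loci) <- NULL
  rownames(samples) <- NULL
  structure(list(calls = calls, loci = loci, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci, %d sites, %.1f%% missing\n",
              nrow(x$calls), ncol(x$calls),
              length(unique(x$samples$site_id)),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Per-sample and per-locus missing fractions
#' @param gm a `genotype_matrix`.
#' @return list with `sample` and `locus` numeric vectors.
#' @export
missing_fractions <- function(gm) {
  list(sample = rowMeans(is.na(gm$calls)),
       locus = colMeans(is.na(gm$calls)))
}

#' Load genotypes from a VCF file
#'
#' Reads a VCF (v4.x, GT field required), keeps biallelic SNP records only,
#' codes genotypes as alternate-allele counts, and attaches site assignments.
#' Records that are not biallelic SNPs are dropped and counted; samples not
#' present in the assignment table are excluded and counted.
#'
#' @param vcf_path path to a VCF file (plain or gzipped).
#' @param site_assignments data.frame with columns `sample_id`, `site_id`
#'   (optionally `lat`, `lon`).
#' @return a `genotype_matrix`; attribute `report` carries drop counts.
#' @export
load_genotypes <- function(vcf_path, site_assignments) {
  if (!file.exists(vcf_path)) stop("cannot read VCF: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1 & nchar(alt) == 1
  n_dropped_records <- sum(!is_snp)
  if (!any(is_snp)) stop("no biallelic SNP records in VCF")
  gt <- vcfR::extract.gt(v[is_snp, ], element = "GT")
  # gt is loci x samples; alleles separated by / or |
  count_alt <- function(g) {
    out <- rep(NA_integer_, length(g))
    ok <- !is.na(g) & !grepl("\\.", g)
    parts <- strsplit(g[ok], "[/|]")
    out[ok] <- vapply(parts, function(p) sum(as.integer(p)), integer(1))
    out
  }
  calls <- t(apply(gt, 2, count_alt))      # samples x loci
  rownames(calls) <- colnames(gt)
  vcf_samples <- rownames(calls)
  keep <- vcf_samples %in% site_assignments$sample_id
  n_dropped_samples <- sum(!keep)
  if (!any(keep)) stop("no VCF samples overlap the site assignment table")
  calls <- calls[keep, , drop = FALSE]
  samples <- data.frame(
    sample_id = rownames(calls),
    site_id = site_assignments$site_id[
      match(rownames(calls), site_assignments$sample_id)],
    stringsAsFactors = FALSE)
  loci <- data.frame(chrom = fix[is_snp, "CHROM"],
                     pos = as.integer(fix[is_snp, "POS"]),
                     ref = ref[is_snp], alt = alt[is_snp],
                     stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, loci, samples)
  attr(gm, "report") <- list(records_dropped = n_dropped_records,
                             samples_dropped = n_dropped_samples)
  gm
}

#' Filter samples and loci by missingness and thin loci by position
#'
#' Three stages in order: (1) remove samples with missing fraction strictly
#' greater than `max_sample_missing`; (2) remove loci with missing fraction
#' strictly greater than `max_locus_missing`; (3) greedy left-to-right
#' position thinning per chromosome, keeping a locus only if it lies more
#' than `min_spacing_bp` from the last kept locus.
#'
#' @param gm a `genotype_matrix`.
#' @param max_sample_missing,max_locus_missing missingness cutoffs
#'   (strict-greater removal), defaults 0.60.
#' @param min_spacing_bp minimum spacing in bp, default 300.
#' @return filtered `genotype_matrix` with attribute `report` listing counts
#'   removed at each stage.
#' @export
filter_and_thin <- function(gm, max_sample_missing = 0.60,
                            max_locus_missing = 0.60, min_spacing_bp = 300) {
  if (nrow(gm$calls) == 0 || ncol(gm$calls) == 0) stop("empty genotype matrix")
  sm <- rowMeans(is.na(gm$calls))
  keep_s <- sm <= max_sample_missing
  if (!any(keep_s)) stop("all samples removed at stage: sample missingness")
  calls <- gm$calls[keep_s, , drop = FALSE]
  lm_ <- colMeans(is.na(calls))
  keep_l <- lm_ <= max_locus_missing
  if (!any(keep_l)) stop("all loci removed at stage: locus missingness")
  calls <- calls[, keep_l, drop = FALSE]
  loci <- gm$loci[keep_l, , drop = FALSE]
  # greedy thinning per chromosome (loci are sorted by chrom, pos)
  keep_t <- logical(nrow(loci))
  for (ch in unique(loci$chrom)) {
    idx <- which(loci$chrom == ch)
    last <- -Inf
    for (i in idx) {
      if (loci$pos[i] - last > min_spacing_bp || !is.finite(last)) {
        keep_t[i] <- TRUE
        last <- loci$pos[i]
      }
    }
  }
  if (!any(keep_t)) stop("all loci removed at stage: thinning")
  out <- genotype_matrix(calls[, keep_t, drop = FALSE],
                         loci[keep_t, , drop = FALSE],
                         gm$samples[keep_s, , drop = FALSE])
  attr(out, "report") <- list(
    samples_removed = sum(!keep_s),
    loci_removed_missing = sum(!keep_l),
    loci_removed_thinning = sum(!keep_t))
  out
}

#' Euclidean genomic distance between samples
#'
#' Pairwise Euclidean distance over alternate-allele counts, computed over
#' loci non-missing in both samples and rescaled by
#' `sqrt(total_loci / shared_loci)` so that distances remain comparable
#' between pairs with different amounts of missing data.
#'
#' @param gm a `genotype_matrix` with at least two samples.
#' @return a `pairwise_matrix` of kind "genomic".
#' @export
genomic_distance_euclidean <- function(gm) {
  x <- gm$calls
  n <- nrow(x)
  if (n < 2) stop("need at least two samples")
  L <- ncol(x)
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0
  # pairwise-complete sums via cross-products of the zero-filled matrix
  shared <- obs %*% t(obs)                       # shared non-missing loci
  sq <- x0^2
  # sum over shared loci of (xi - xj)^2 =
  #   sum(xi^2 over j-observed) + sum(xj^2 over i-observed) - 2 xi.xj
  s_i <- sq %*% t(obs)
  cross <- x0 %*% t(x0)
  d2 <- s_i + t(s_i) - 2 * cross
  zero_shared <- shared == 0 & upper.tri(shared)
  if (any(zero_shared)) {
    ij <- which(zero_shared, arr.ind = TRUE)[1, ]
    stop(sprintf("samples %s and %s share no non-missing loci",
                 rownames(x)[ij[1]], rownames(x)[ij[2]]))
  }
  scale2 <- L / shared
  diag(scale2) <- 1
  d <- sqrt(pmax(d2 * scale2, 0))
  pairwise_matrix(d, labels = rownames(x), kind = "genomic")
}

#' Per-site allelic diversity and expected heterozygosity
#'
#' For each site: the number of distinct alleles observed across loci and
#' the expected heterozygosity He, the mean over loci (with at least one
#' called genotype at the site) of `1 - p^2 - q^2`.
#'
#' @param gm a `genotype_matrix`.
#' @return data.frame with columns `site_id`, `n_samples`, `n_alleles`, `He`.
#' @export
site_diversity <- function(gm) {
  sites <- unique(gm$samples$site_id)
  out <- lapply(sites, function(s) {
    rows <- gm$samples$site_id == s
    x <- gm$calls[rows, , drop = FALSE]
    n_called <- colSums(!is.na(x))
    alt <- colSums(x, na.rm = TRUE)
    p_alt <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
    has <- n_called > 0
    n_alleles <- sum((p_alt[has] > 0) + (p_alt[has] < 1))
    he <- mean(1 - p_alt[has]^2 - (1 - p_alt[has])^2)
    data.frame(site_id = s, n_samples = sum(rows),
               n_alleles = n_alleles, He = he, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Scale an Fst matrix to the unit interval
#'
#' Maps off-diagonal values v to `(v - min) / (max - min)` so the minimum
#' becomes 0 and the maximum 1; the diagonal is forced to 0. Slightly
#' negative Fst estimates are handled naturally (the minimum maps to 0).
#'
#' @param fst a `pairwise_matrix` of kind "fst".
#' @return a `pairwise_matrix` of kind "scaled_fst".
#' @export
scale_unit_interval <- function(fst) {
  v <- lower_tri(fst)
  rng <- range(v)
  if (diff(rng) <= 0) stop("degenerate scaling: all off-diagonal values equal")
  m <- (unclass(fst) - rng[1]) / diff(rng)
  diag(m) <- 0
  pairwise_matrix(m, labels = rownames(fst), kind = "scaled_fst")
}
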