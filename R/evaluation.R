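#' Reciprocal overlap of two intervals
#'
#' Returns the overlap length divided by each interval's length. Two
#' intervals match when both fractions reach `reciprocal` (default 0.5) or
#' either interval is covered to at least `coverage` (default 0.9) by the
#' other.
#'
#' @param a,b Length-2 numeric vectors `c(start, end)`, 0-based half-open,
#'   assumed on the same chromosome.
#' @param reciprocal,coverage Matching thresholds.
#' @return List with `frac_a`, `frac_b`, `match`.
#' @export
reciprocal_overlap <- function(a, b, reciprocal = 0.5, coverage = 0.9) {
  la <- a[2] - a[1]; lb <- b[2] - b[1]
  if (la <= 0 || lb <= 0) stop("zero-length interval")
  ov <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  fa <- ov / la; fb <- ov / lb
  list(frac_a = fa, frac_b = fb,
       match = (fa >= reciprocal && fb >= reciprocal) ||
               fa >= coverage || fb >= coverage)
}

# all matching (query, ref) pairs under the reciprocal/coverage rule
.match_intervals <- function(query, ref, reciprocal = 0.5, coverage = 0.9) {
  if (nrow(query) == 0L || nrow(ref) == 0L)
    return(data.frame(query = integer(0), ref = integer(0)))
  gq <- GenomicRanges::GRanges(query$chrom,
                               IRanges::IRanges(query$start + 1L, query$end))
  gr <- GenomicRanges::GRanges(ref$chrom,
                               IRanges::IRanges(ref$start + 1L, ref$end))
  h <- GenomicRanges::findOverlaps(gq, gr)
  if (length(h) == 0L)
    return(data.frame(query = integer(0), ref = integer(0)))
  qi <- S4Vectors::queryHits(h); ri <- S4Vectors::subjectHits(h)
  ov <- BiocGenerics::width(IRanges::pintersect(
    IRanges::ranges(gq)[qi], IRanges::ranges(gr)[ri]))
  fa <- ov / (query$end[qi] - query$start[qi])
  fb <- ov / (ref$end[ri] - ref$start[ri])
  ok <- (fa >= reciprocal & fb >= reciprocal) | fa >= coverage | fb >= coverage
  data.frame(query = qi[ok], ref = ri[ok])
}

#' Sensitivity of a callset against a truth database
#'
#' Both sets are filtered to length > `min_len` and allele frequency >=
#' `min_af`, then the fraction of truth entries matched by at least one
#' call under the >=50\% reciprocal overlap (or >=90\% coverage) rule is
#' returned.
#'
#' @param calls,truth Data frames with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `af`.
#' @param min_len Minimum interval length (default 2500; entries of
#'   exactly this length are removed).
#' @param min_af Minimum allele frequency (default 0.05); applied only
#'   where an `af` column exists.
#' @param reciprocal,coverage Matching thresholds.
#' @return Fraction of truth entries recovered.
#' @export
sensitivity <- function(calls, truth, min_len = 2500, min_af = 0.05,
                        reciprocal = 0.5, coverage = 0.9) {
  filt <- function(df) {
    keep <- (df$end - df$start) > min_len
    if (!is.null(df$af)) keep <- keep & !is.na(df$af) & df$af >= min_af
    df[keep, , drop = FALSE]
  }
  truth <- filt(truth)
  if (nrow(truth) == 0L) stop("no truth entries pass the length/frequency filter")
  calls <- filt(calls)
  if (nrow(calls) == 0L) return(0)
  m <- .match_intervals(calls, truth, reciprocal, coverage)
  length(unique(m$ref)) / nrow(truth)
}

# diploid allele pairs compatible with an integer CN under the biallelic
# model: losses use alleles {d = 0 copies, r = 1}, gains {r = 1, D = 2}
.cn_alleles <- function(cn, type) {
  if (type == "loss") {
    switch(as.character(cn), "0" = list(c(0L, 0L)), "1" = list(c(0L, 1L)),
           "2" = list(c(1L, 1L)), NULL)
  } else {
    switch(as.character(cn), "2" = list(c(1L, 1L)), "3" = list(c(1L, 2L)),
           "4" = list(c(2L, 2L)), NULL)
  }
}

#' Mendelian inconsistency of trio genotypes
#'
#' For every biallelic deleted or duplicated region (maximum copy number
#' <= 4; mixed regions excluded) and every trio, the child's integer copy
#' number is consistent when some transmission — one allele from each
#' parent under the CN-to-allele mapping (loss: 0 = d/d, 1 = d/r,
#' 2 = r/r; gain: 2 = r/r, 3 = r/D, 4 = D/D) — reproduces it. The
#' inconsistent fraction over all scored trio-by-region pairs approximates
#' the false discovery rate.
#'
#' @param vcf Path to a CNV VCF, or the output of [read_cnv_vcf()].
#' @param pedigree Data frame with columns `family`, `child`, `father`,
#'   `mother`.
#' @return List with `fraction`, `n_scored`, `n_inconsistent` and
#'   `per_region` (data.frame with per-region inconsistent counts).
#' @export
mendelian_inconsistency <- function(vcf, pedigree) {
  if (is.character(vcf)) vcf <- read_cnv_vcf(vcf)
  need <- unique(c(pedigree$child, pedigree$father, pedigree$mother))
  missing <- setdiff(need, rownames(vcf$cn))
  if (length(missing))
    stop("pedigree samples missing from the VCF: ",
         paste(missing, collapse = ", "))
  calls <- vcf$calls
  n_rec <- nrow(calls)
  scored <- inconsistent <- integer(n_rec)
  for (k in seq_len(n_rec)) {
    type <- calls$type[k]
    if (!type %in% c("loss", "gain")) next
    cn_k <- vcf$cn[, k]
    rng <- if (type == "loss") 0:2 else 2:4
    if (any(!stats::na.omit(cn_k) %in% rng)) next   # not biallelic / CN > 4
    for (tr in seq_len(nrow(pedigree))) {
      cf <- cn_k[pedigree$father[tr]]
      cm <- cn_k[pedigree$mother[tr]]
      cc <- cn_k[pedigree$child[tr]]
      if (anyNA(c(cf, cm, cc))) next
      fa <- .cn_alleles(cf, type)[[1]]
      mo <- .cn_alleles(cm, type)[[1]]
      ch <- .cn_alleles(cc, type)[[1]]
      ok <- FALSE
      for (x in fa) for (y in mo)
        if (identical(sort(c(x, y)), sort(ch))) ok <- TRUE
      scored[k] <- scored[k] + 1L
      if (!ok) inconsistent[k] <- inconsistent[k] + 1L
    }
  }
  n_scored <- sum(scored)
  list(fraction = if (n_scored > 0) sum(inconsistent) / n_scored else NA_real_,
       n_scored = n_scored, n_inconsistent = sum(inconsistent),
       per_region = data.frame(chrom = calls$chrom, start = calls$start,
                               end = calls$end, type = calls$type,
                               scored = scored, inconsistent = inconsistent))
}

#' Genotype concordance between two callsets
#'
#' Over region pairs matched at >= `coverage_fraction` reciprocal overlap,
#' the fraction of shared-sample integer copy numbers in exact agreement.
#'
#' @param vcf_a,vcf_b Paths to CNV VCFs or outputs of [read_cnv_vcf()].
#' @param coverage_fraction Reciprocal overlap required to pair two
#'   records (default 0.9).
#' @return List with `fraction`, `n_pairs`, `n_genotypes`.
#' @export
genotype_concordance <- function(vcf_a, vcf_b, coverage_fraction = 0.9) {
  if (is.character(vcf_a)) vcf_a <- read_cnv_vcf(vcf_a)
  if (is.character(vcf_b)) vcf_b <- read_cnv_vcf(vcf_b)
  shared <- intersect(rownames(vcf_a$cn), rownames(vcf_b$cn))
  if (length(shared) == 0L) stop("no shared samples")
  m <- .match_intervals(vcf_a$calls, vcf_b$calls,
                        reciprocal = coverage_fraction, coverage = Inf)
  if (nrow(m) == 0L) stop("no region pairs matched at the required overlap")
  agree <- total <- 0L
  for (p in seq_len(nrow(m))) {
    ca <- vcf_a$cn[shared, m$query[p]]
    cb <- vcf_b$cn[shared, m$ref[p]]
    ok <- !is.na(ca) & !is.na(cb)
    agree <- agree + sum(ca[ok] == cb[ok])
    total <- total + sum(ok)
  }
  list(fraction = agree / total, n_pairs = nrow(m), n_genotypes = total)
}
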