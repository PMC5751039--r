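#' Continuous copy number estimates for one CNV region
#'
#' A sample's copy number is initially estimated as 2 times the median of
#' its normalized depths over the region's member candidate windows
#' (tolerated non-candidate windows are never members, so they do not
#' enter the median).
#'
#' @param cnvrs A `cnvr_set`.
#' @param k Region number (column of the set).
#' @return Numeric vector of continuous copy number estimates per sample.
#' @export
estimate_copy_numbers <- function(cnvrs, k) {
  stopifnot(inherits(cnvrs, "cnvr_set"), k >= 1L, k <= ncol(cnvrs$depth))
  2 * cnvrs$depth[, k]
}

#' Fit a Dirichlet-process Gaussian mixture to copy number estimates
#'
#' Clusters one region's continuous copy number estimates into Gaussian
#' components with the component count inferred by a truncated
#' stick-breaking Dirichlet process (variational EM: Beta posteriors on
#' the stick weights, point estimates for the component means and
#' variances). Components whose posterior weight falls below
#' `weight_floor`, and components closer than `merge_tol` to a heavier
#' one, are removed and the fit is polished. Each sample's integer copy
#' number is the rounded mean of its assigned component, so every member
#' of a cluster shares one integer CN. Clustering quality is scored by the
#' mean silhouette width over the assignment (1-D Euclidean distance);
#' with a single component the silhouette is undefined and the result is
#' flagged `"single-cluster"`.
#'
#' @param cn_estimates Numeric vector of continuous CN estimates (>= 2).
#' @param max_components Truncation level of the stick-breaking process.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param alpha Dirichlet-process concentration (default 1).
#' @param weight_floor Minimum effective component weight; default
#'   `1 / (10 * max_components * n)` scaled as 1/(10 n) per component slot.
#' @param merge_tol Components with means closer than this collapse into
#'   one (default 0.25, half the smallest CN separation worth genotyping).
#' @return A `cnv_genotype`: estimates, integer CNs, component assignment,
#'   means, sds, weights, `n_components`, `silhouette`, `quality`.
#' @export
fit_mixture <- function(cn_estimates, max_components = 10L, seed = 1L,
                        alpha = 1, weight_floor = NULL, merge_tol = 0.25) {
  x <- as.numeric(cn_estimates)
  n <- length(x)
  if (n < 2L) stop("need >= 2 samples to genotype")
  if (any(!is.finite(x))) stop("non-finite copy number estimates")
  if (is.null(weight_floor)) weight_floor <- 1 / (10 * n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  fit <- .dpgmm_1d(x, T = as.integer(max_components), alpha = alpha)
  # prune: weight floor, then near-duplicate means
  repeat {
    keep <- fit$weight > weight_floor
    if (!any(keep)) keep[which.max(fit$weight)] <- TRUE
    fit <- .gmm_refit(x, fit$mu[keep], fit$sigma2[keep], fit$weight[keep])
    o <- order(fit$weight, decreasing = TRUE)
    drop <- rep(FALSE, length(fit$mu))
    for (a in seq_along(o)) if (!drop[o[a]]) {
      close <- which(!drop & abs(fit$mu - fit$mu[o[a]]) < merge_tol)
      drop[setdiff(close, o[a])] <- TRUE
    }
    if (!any(drop) && all(fit$weight > weight_floor)) break
    fit <- .gmm_refit(x, fit$mu[!drop], fit$sigma2[!drop], fit$weight[!drop])
    if (length(fit$mu) == 1L) break
  }

  o <- order(fit$mu)
  mu <- fit$mu[o]; sigma2 <- fit$sigma2[o]; weight <- fit$weight[o]
  weight <- weight / sum(weight)
  assign <- apply(.gmm_resp(x, mu, sigma2, weight), 1, which.max)
  cn_comp <- pmax(0L, as.integer(floor(mu + 0.5)))   # half-up, floored at 0
  cn_int <- cn_comp[assign]
  kk <- length(mu)
  if (kk > 1L && length(unique(assign)) > 1L) {
    so <- cluster::silhouette(assign, stats::dist(x))
    # silhouette is undefined when every cluster is a singleton
    sil <- if (is.matrix(so)) mean(so[, "sil_width"]) else NA_real_
    quality <- "multi-cluster"
  } else {
    sil <- NA_real_
    quality <- "single-cluster"
  }
  structure(list(cn_est = x, cn_int = cn_int, assignment = assign,
                 means = mu, sds = sqrt(sigma2), weights = weight,
                 n_components = kk, silhouette = sil, quality = quality),
            class = "cnv_genotype")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# responsibilities of a finite 1-D Gaussian mixture
.gmm_resp <- function(x, mu, sigma2, weight) {
  lp <- vapply(seq_along(mu), function(k)
    log(weight[k] + 1e-300) + stats::dnorm(x, mu[k], sqrt(sigma2[k]), log = TRUE),
    numeric(length(x)))
  lp <- matrix(lp, nrow = length(x))
  m <- apply(lp, 1, max)
  r <- exp(lp - m)
  r / rowSums(r)
}

# truncated stick-breaking variational EM; deterministic quantile init
.dpgmm_1d <- function(x, T = 10L, alpha = 1, max_iter = 200L, tol = 1e-8) {
  n <- length(x)
  T <- max(1L, min(T, n))
  var_floor <- max(1e-6, stats::var(x) * 1e-6)
  mu <- as.numeric(stats::quantile(x, probs = (seq_len(T) - 0.5) / T,
                                   type = 1))
  sigma2 <- rep(max(stats::var(x) / T^2, var_floor), T)
  elogpi <- rep(log(1 / T), T)
  r_old <- NULL
  for (it in seq_len(max_iter)) {
    lp <- vapply(seq_len(T), function(k)
      elogpi[k] + stats::dnorm(x, mu[k], sqrt(sigma2[k]), log = TRUE),
      numeric(n))
    lp <- matrix(lp, nrow = n)
    mx <- apply(lp, 1, max)
    r <- exp(lp - mx); r <- r / rowSums(r)
    Nk <- colSums(r)
    # Beta posteriors on the stick fractions
    g1 <- 1 + Nk
    g2 <- alpha + rev(cumsum(rev(Nk)))[-1]
    g2 <- c(g2, alpha)
    elogv <- digamma(g1) - digamma(g1 + g2)
    elog1mv <- digamma(g2) - digamma(g1 + g2)
    elogpi <- elogv + c(0, cumsum(elog1mv)[-T])
    upd <- Nk > 1e-10
    mu[upd] <- (colSums(r * x))[upd] / Nk[upd]
    sq <- colSums(r * (matrix(x, n, T) - matrix(mu, n, T, byrow = TRUE))^2)
    sigma2[upd] <- pmax(sq[upd] / Nk[upd], var_floor)
    if (!is.null(r_old) && mean(abs(r - r_old)) < tol) break
    r_old <- r
  }
  list(mu = mu, sigma2 = sigma2, weight = Nk / n)
}

# plain EM polish of a finite mixture after pruning/merging
.gmm_refit <- function(x, mu, sigma2, weight, max_iter = 100L, tol = 1e-8) {
  n <- length(x)
  weight <- weight / sum(weight)
  var_floor <- max(1e-6, stats::var(x) * 1e-6)
  if (length(mu) == 1L)
    return(list(mu = mean(x), sigma2 = max(stats::var(x), var_floor),
                weight = 1))
  r_old <- NULL
  for (it in seq_len(max_iter)) {
    r <- .gmm_resp(x, mu, sigma2, weight)
    Nk <- colSums(r)
    upd <- Nk > 1e-10
    mu[upd] <- (colSums(r * x))[upd] / Nk[upd]
    sq <- colSums(r * (matrix(x, n, length(mu)) -
                       matrix(mu, n, length(mu), byrow = TRUE))^2)
    sigma2[upd] <- pmax(sq[upd] / Nk[upd], var_floor)
    weight <- Nk / n
    if (!is.null(r_old) && mean(abs(r - r_old)) < tol) break
    r_old <- r
  }
  list(mu = mu, sigma2 = sigma2, weight = weight)
}

#' @export
print.cnv_genotype <- function(x, ...) {
  cat(sprintf("cnv_genotype: %d samples, %d component(s), silhouette %s (%s)\n",
              length(x$cn_est), x$n_components,
              ifelse(is.na(x$silhouette), "NA", sprintf("%.3f", x$silhouette)),
              x$quality))
  cat("  component means:", sprintf("%.3f", x$means), "\n")
  cat("  integer CN table:")
  print(table(x$cn_int))
  invisible(x)
}

#' Genotype every region of a CNVR set
#'
#' Regions are genotyped independently (any execution order gives the same
#' output); region `k` is fitted with seed `seed + k` so the whole callset
#' is reproducible from one seed.
#'
#' @param cnvrs A `cnvr_set`.
#' @param seed Base integer seed.
#' @param max_components Passed to [fit_mixture()].
#' @return List of `cnv_genotype`, one per region.
#' @export
genotype_cnvrs <- function(cnvrs, seed = 1L, max_components = 10L) {
  stopifnot(inherits(cnvrs, "cnvr_set"))
  lapply(seq_len(ncol(cnvrs$depth)), function(k)
    fit_mixture(estimate_copy_numbers(cnvrs, k),
                max_components = max_components, seed = seed + k))
}

#' Write genotyped CNV regions as VCF 4.2
#'
#' One record per region with a symbolic ALT (`<DEL>`, `<DUP>`, or both for
#' mixed regions), INFO `END`, `SVTYPE`, `SVLEN`, `AF` and `SIL`
#' (silhouette), and per-sample `GT:CN`. GT is derived from the integer CN
#' for biallelic regions (loss: 2 -> 0/0, 1 -> 0/1, 0 -> 1/1; gain with
#' max CN <= 4: 2 -> 0/0, 3 -> 0/1, 4 -> 1/1); any other configuration gets
#' `./.` with the CN still carried. Positions are converted to 1-based.
#'
#' @param results List of `cnv_genotype` aligned to the regions.
#' @param cnvrs The `cnvr_set`.
#' @param path Output VCF path.
#' @export
write_vcf <- function(results, cnvrs, path) {
  stopifnot(length(results) == nrow(cnvrs$calls))
  ids <- cnvrs$sample_ids
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=cnvpop",
    "##ALT=<ID=DEL,Description=\"Deletion relative to the reference\">",
    "##ALT=<ID=DUP,Description=\"Duplication relative to the reference\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternative allele frequency\">",
    "##INFO=<ID=SIL,Number=1,Type=Float,Description=\"Genotyping silhouette coefficient\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=CN,Number=1,Type=Integer,Description=\"Integer copy number\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  df <- cnvrs$calls
  o <- order(match(df$chrom, unique(df$chrom)), df$start)
  recs <- vapply(o, function(k) {
    r <- results[[k]]
    type <- df$type[k]
    alt <- switch(type, loss = "<DEL>", gain = "<DUP>", "<DEL>,<DUP>")
    svtype <- switch(type, loss = "DEL", gain = "DUP", "CNV")
    len <- df$end[k] - df$start[k]
    svlen <- if (type == "loss") -len else len
    info <- sprintf("END=%d;SVTYPE=%s;SVLEN=%d;AF=%.4f", df$end[k], svtype,
                    svlen, df$af[k])
    if (is.finite(r$silhouette))
      info <- sprintf("%s;SIL=%.4f", info, r$silhouette)
    gt <- .cn_to_gt(r$cn_int, type)
    smp <- sprintf("%s:%d", gt, r$cn_int)
    paste(c(df$chrom[k], df$start[k] + 1L, sprintf("cnvr_%d", k), "N", alt,
            ".", "PASS", info, "GT:CN", smp), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

.cn_to_gt <- function(cn, type) {
  if (type == "loss" && all(cn <= 2L)) {
    c("1/1", "0/1", "0/0")[cn + 1L]
  } else if (type == "gain" && all(cn >= 2L) && max(cn) <= 4L) {
    c("0/0", "0/1", "1/1")[cn - 1L]
  } else {
    rep("./.", length(cn))
  }
}

#' Read a CNV VCF back into calls and copy number matrices
#'
#' Parses a VCF written by [write_vcf()] (or any VCF with symbolic CNV
#' records carrying INFO END/SVTYPE/AF and FORMAT CN).
#'
#' @param path VCF path.
#' @return List with `calls` (data.frame `chrom`, `start` (0-based), `end`,
#'   `type`, `af`, `sil`), `cn` (samples x records integer matrix) and `gt`
#'   (character matrix).
#' @export
read_cnv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))                 # single-record VCFs drop to a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  info1 <- function(key) vcfR::extract.info(v, element = key)
  svtype <- info1("SVTYPE")
  type <- ifelse(svtype == "DEL", "loss", ifelse(svtype == "DUP", "gain", "mixed"))
  calls <- data.frame(
    chrom = fix[, "CHROM"],
    start = as.integer(fix[, "POS"]) - 1L,
    end = as.integer(info1("END")),
    type = type,
    af = suppressWarnings(as.numeric(info1("AF"))),
    sil = suppressWarnings(as.numeric(info1("SIL"))),
    stringsAsFactors = FALSE)
  cn <- vcfR::extract.gt(v, element = "CN")
  gt <- vcfR::extract.gt(v, element = "GT")
  cn <- t(matrix(as.integer(cn), nrow = nrow(cn), dimnames = dimnames(cn)))
  gt <- t(gt)
  list(calls = calls, cn = cn, gt = gt)
}
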