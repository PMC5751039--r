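#' Assemble per-sample profiles into a population depth matrix
#'
#' Stacks normalized per-sample profiles (all built on the same window
#' grid) into a samples x windows matrix and records each sample's
#' genome-wide mean and standard deviation of normalized depth, which the
#' individual candidate criterion uses.
#'
#' @param profiles List of normalized `sample_profile` objects.
#' @param grid The shared `window_grid`.
#' @return A `population_matrix`: list with `sample_ids`, `depth` (matrix),
#'   `mean`, `sd`, and the grid.
#' @export
assemble_matrix <- function(profiles, grid) {
  stopifnot(inherits(grid, "window_grid"))
  if (length(profiles) < 2L) stop("need at least 2 samples")
  for (p in profiles) {
    if (!inherits(p, "sample_profile")) stop("profiles must be sample_profile objects")
    if (p$window_size != attr(grid, "window_size") ||
        p$n_windows != nrow(grid))
      stop("sample '", p$sample_id, "' was built on a different grid (window_size ",
           p$window_size, ", ", p$n_windows, " windows)")
  }
  depth <- do.call(rbind, lapply(profiles, `[[`, "depths"))
  ids <- vapply(profiles, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  rownames(depth) <- ids
  structure(list(sample_ids = ids, depth = depth,
                 mean = rowMeans(depth), sd = apply(depth, 1, stats::sd),
                 sex = vapply(profiles, `[[`, character(1), "sex"),
                 grid = grid, flags = NULL, candidate = NULL, af = NULL,
                 mode = NULL),
            class = "population_matrix")
}

#' @export
print.population_matrix <- function(x, ...) {
  cat(sprintf("population_matrix: %d samples x %d windows (%d-bp windows)\n",
              nrow(x$depth), ncol(x$depth), attr(x$grid, "window_size")))
  if (!is.null(x$flags))
    cat(sprintf("  flagged (mode %s): %d het, %d hom sample-windows\n",
                x$mode, sum(abs(x$flags) == 1L), sum(abs(x$flags) == 2L)))
  if (!is.null(x$candidate))
    cat(sprintf("  candidate windows: %d\n", sum(x$candidate)))
  invisible(x)
}

# flag codes: 0 normal, -1 het_loss, -2 hom_loss, +1 het_gain, +2 hom_gain
.flag_depths <- function(depth, smean, ssd, mode) {
  het_lo <- if (mode == "selfbred") 0.25 else 0.65
  het_hi <- if (mode == "selfbred") 1.75 else 1.35
  lo <- depth < smean - 2 * ssd
  hi <- depth > smean + 2 * ssd
  f <- matrix(0L, nrow(depth), ncol(depth))
  f[lo & depth < het_lo] <- -1L
  f[hi & depth > het_hi] <- 1L
  f[depth < 0.25] <- -2L
  f[depth > 1.75] <- 2L
  f
}

#' Flag individual candidate CNV windows
#'
#' A window is a heterozygous loss candidate for a sample when its depth is
#' both significantly low (below mean - 2 SD of that sample's genome-wide
#' depth) and below the empirical heterozygous-deletion bound; gains are
#' symmetric. Depths below 0.25 / above 1.75 are homozygous candidates
#' regardless of the SD criterion. The `selfbred` mode replaces the 0.65 /
#' 1.35 empirical bounds with the homozygous 0.25 / 1.75 bounds (selfing
#' species carry essentially homozygous CNVs).
#'
#' @param pm A `population_matrix`.
#' @param mode `"outbred"` (default) or `"selfbred"`.
#' @return The matrix with a `flags` integer matrix added (0 normal,
#'   -1/-2 het/hom loss, +1/+2 het/hom gain).
#' @export
flag_individual_candidates <- function(pm, mode = c("outbred", "selfbred")) {
  stopifnot(inherits(pm, "population_matrix"))
  mode <- match.arg(mode)
  pm$flags <- .flag_depths(pm$depth, pm$mean, pm$sd, mode)
  dimnames(pm$flags) <- dimnames(pm$depth)
  pm$mode <- mode
  pm
}

#' Select population-level candidate CNV windows
#'
#' A window is kept when its alternative allele frequency — counted as
#' (het carriers + 2 hom carriers) / (2 N) — reaches `min_af`, or at least
#' `min_hom` samples are homozygous carriers. With `keep_all_het = TRUE`
#' every window with any non-normal sample is kept instead (small or
#' high-coverage cohorts).
#'
#' @param pm A flagged `population_matrix`.
#' @param min_af Minimum alternative allele frequency (default 0.05).
#' @param min_hom Minimum homozygous carriers (default 2).
#' @param keep_all_het Keep any window with >= 1 carrier.
#' @return The matrix with `candidate` (logical per window) and `af`
#'   (numeric per window) added.
#' @export
select_population_windows <- function(pm, min_af = 0.05, min_hom = 2L,
                                      keep_all_het = FALSE) {
  stopifnot(inherits(pm, "population_matrix"))
  if (is.null(pm$flags)) stop("run flag_individual_candidates() first")
  n <- nrow(pm$depth)
  n_het <- colSums(abs(pm$flags) == 1L)
  n_hom <- colSums(abs(pm$flags) == 2L)
  af <- (n_het + 2 * n_hom) / (2 * n)
  sel <- af >= min_af | n_hom >= min_hom
  if (keep_all_het) sel <- sel | (n_het + n_hom) >= 1L
  pm$candidate <- sel
  pm$af <- af
  pm
}

#' Pearson correlation of two windows' population depths
#'
#' Correlation across samples between two nonoverlapping windows, tested
#' with the Student t statistic `t = r sqrt(n-2) / sqrt(1-r^2)` on n-2
#' degrees of freedom (two-sided). A zero-variance column makes the
#' correlation undefined and is reported as not significant.
#'
#' @param pm A `population_matrix`.
#' @param window_a,window_b Window column positions (rows of the grid).
#' @param p_threshold Significance level (default 0.01).
#' @return List with `r`, `p`, `significant`.
#' @export
adjacent_correlation <- function(pm, window_a, window_b, p_threshold = 0.01) {
  stopifnot(inherits(pm, "population_matrix"))
  n <- nrow(pm$depth)
  if (n < 4L) stop("need >= 4 samples for the correlation t-test (df = n - 2)")
  g <- pm$grid
  if (g$chrom[window_a] == g$chrom[window_b] &&
      max(g$start[window_a], g$start[window_b]) <
      min(g$end[window_a], g$end[window_b]))
    stop("windows overlap; the correlation criterion uses nonoverlapping windows")
  .cor_test(pm$depth[, window_a], pm$depth[, window_b], p_threshold)
}

.cor_test <- function(x, y, p_threshold = 0.01) {
  n <- length(x)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0)
    return(list(r = NA_real_, p = NA_real_, significant = FALSE))
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0, significant = TRUE))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(r = r, p = p, significant = p < p_threshold)
}

#' Apply the adjacent-window correlation criterion
#'
#' Keeps a candidate window only if its population depths correlate
#' significantly (Pearson, t-test at `p_threshold`) with an adjacent
#' nonoverlapping candidate window — the window one full window away
#' (two grid steps) on either side. Zero-variance columns, where the
#' correlation is undefined, are kept: membership then relies on the run
#' rule alone.
#'
#' @param pm A `population_matrix` with candidates selected.
#' @param p_threshold Significance level (default 0.01).
#' @return The matrix with `candidate` filtered.
#' @export
apply_correlation_criterion <- function(pm, p_threshold = 0.01) {
  stopifnot(inherits(pm, "population_matrix"))
  if (is.null(pm$candidate)) stop("run select_population_windows() first")
  if (nrow(pm$depth) < 4L) return(pm)   # t-test undefined; criterion skipped
  g <- pm$grid
  cand <- which(pm$candidate)
  if (!length(cand)) return(pm)
  # column position of the window exactly two pre-filter indices away
  pos_of <- integer(max(g$index))
  pos_of[g$index] <- seq_len(nrow(g))
  keep <- logical(length(cand))
  for (ii in seq_along(cand)) {
    i <- cand[ii]
    x <- pm$depth[, i]
    if (stats::sd(x) == 0) { keep[ii] <- TRUE; next }
    for (d in c(-2L, 2L)) {
      j_idx <- g$index[i] + d
      if (j_idx < 1L || j_idx > length(pos_of)) next
      j <- pos_of[j_idx]
      if (j == 0L || !pm$candidate[j] || g$chrom[j] != g$chrom[i]) next
      ct <- .cor_test(x, pm$depth[, j], p_threshold)
      if (ct$significant && !is.na(ct$r) && ct$r > 0) {
        keep[ii] <- TRUE; break
      }
    }
  }
  pm$candidate[cand[!keep]] <- FALSE
  pm
}

#' Define initial CNV regions from candidate windows
#'
#' Scans each chromosome for runs of consecutive candidate windows. A run
#' may tolerate isolated non-candidate windows, at most one in any four
#' consecutive positions; tolerated windows are excluded from region depth.
#' A run becomes an initial call when it spans at least `min_run` grid
#' positions ("more than 4 sequential overlapping windows"). Windows
#' removed by the gap filter break runs (gap-split regions are rejoined by
#' [merge_adjacent_cnvrs()]).
#'
#' @param pm A `population_matrix` with candidates selected.
#' @param min_run Minimum run span in windows (default 5).
#' @return A `cnvr_set`: list with `calls` (data.frame `chrom`, `start`,
#'   `end`, `type`, `n_windows`, `af`), `members` (list of member window
#'   columns per call) and `depth` (samples x calls median region depth).
#' @export
define_cnvrs <- function(pm, min_run = 5L) {
  stopifnot(inherits(pm, "population_matrix"))
  if (is.null(pm$candidate)) stop("run select_population_windows() first")
  g <- pm$grid
  members <- list()
  n <- nrow(g)
  run <- integer(0)        # candidate member columns of the open run
  last_skip <- -Inf        # pre-filter index of the last tolerated skip
  close_run <- function() {
    if (length(run)) {
      span <- g$index[run[length(run)]] - g$index[run[1]] + 1L
      if (span >= min_run) members[[length(members) + 1L]] <<- run
    }
    run <<- integer(0); last_skip <<- -Inf
  }
  prev_idx <- -Inf; prev_chrom <- ""
  for (i in seq_len(n)) {
    idx <- g$index[i]
    contiguous <- g$chrom[i] == prev_chrom && idx == prev_idx + 1L
    if (!contiguous && length(run)) close_run()
    if (pm$candidate[i]) {
      run <- c(run, i)
    } else if (length(run)) {
      # tolerate one unselected window out of any 4 consecutive positions,
      # and never two in a row
      if (idx - last_skip < 4L) close_run()
      else last_skip <- idx
    }
    prev_idx <- idx; prev_chrom <- g$chrom[i]
  }
  if (length(run)) close_run()
  .build_cnvr_set(pm, members)
}

.region_type <- function(flags, member_cols) {
  f <- flags[, member_cols, drop = FALSE]
  has_loss <- any(f < 0L); has_gain <- any(f > 0L)
  if (has_loss && has_gain) "mixed" else if (has_loss) "loss"
  else if (has_gain) "gain" else "mixed"
}

.region_af <- function(depth_col, smean, ssd, mode) {
  f <- .flag_depths(matrix(depth_col, ncol = 1), smean, ssd, mode)
  (sum(abs(f) == 1L) + 2 * sum(abs(f) == 2L)) / (2 * length(depth_col))
}

.build_cnvr_set <- function(pm, members) {
  g <- pm$grid
  mode <- if (is.null(pm$mode)) "outbred" else pm$mode
  if (length(members) == 0L) {
    calls <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), type = character(0),
                        n_windows = integer(0), af = numeric(0))
    return(structure(list(calls = calls, members = list(),
                          depth = matrix(numeric(0), nrow(pm$depth), 0,
                                         dimnames = list(pm$sample_ids, NULL)),
                          sample_ids = pm$sample_ids),
                     class = "cnvr_set"))
  }
  depth <- vapply(members, function(m)
    apply(pm$depth[, m, drop = FALSE], 1, stats::median), numeric(nrow(pm$depth)))
  depth <- matrix(depth, nrow = nrow(pm$depth),
                  dimnames = list(pm$sample_ids, NULL))
  calls <- data.frame(
    chrom = vapply(members, function(m) g$chrom[m[1]], character(1)),
    start = vapply(members, function(m) g$start[m[1]], integer(1)),
    end = vapply(members, function(m) g$end[m[length(m)]], integer(1)),
    type = vapply(members, function(m)
      .region_type(pm$flags, m), character(1)),
    n_windows = lengths(members),
    af = vapply(seq_along(members), function(k)
      .region_af(depth[, k], pm$mean, pm$sd, mode), numeric(1)),
    stringsAsFactors = FALSE)
  o <- order(match(calls$chrom, names(attr(g, "seqlengths"))), calls$start)
  structure(list(calls = calls[o, , drop = FALSE],
                 members = members[o],
                 depth = depth[, o, drop = FALSE],
                 sample_ids = pm$sample_ids),
            class = "cnvr_set")
}

#' @export
print.cnvr_set <- function(x, ...) {
  cat(sprintf("cnvr_set: %d region(s), %d sample(s)\n",
              nrow(x$calls), length(x$sample_ids)))
  if (nrow(x$calls)) print.data.frame(utils::head(x$calls, 10))
  invisible(x)
}

#' Merge adjacent correlated CNV regions
#'
#' Assemblies fragment true regions with gaps; two same-chromosome calls
#' are merged when the distance between them is below `max_gap_frac` of
#' their combined length and their per-sample region depths are
#' significantly positively Pearson-correlated (t-test at `p_threshold`;
#' anti-correlated fragments stay separate). The sweep is
#' strictly left to right and repeats until no pair merges.
#'
#' @param cnvrs A `cnvr_set` from [define_cnvrs()].
#' @param pm The `population_matrix` the calls came from.
#' @param max_gap_frac Maximum gap as a fraction of combined length (0.2).
#' @param p_threshold Correlation significance level (0.01).
#' @return The merged `cnvr_set`.
#' @export
merge_adjacent_cnvrs <- function(cnvrs, pm, max_gap_frac = 0.2,
                                 p_threshold = 0.01) {
  stopifnot(inherits(cnvrs, "cnvr_set"), inherits(pm, "population_matrix"))
  members <- cnvrs$members
  if (length(members) < 2L) return(cnvrs)
  g <- pm$grid
  repeat {
    merged_any <- FALSE
    out <- list()
    k <- 1L
    while (k <= length(members)) {
      cur <- members[[k]]
      while (k < length(members)) {
        nxt <- members[[k + 1L]]
        same <- g$chrom[cur[1]] == g$chrom[nxt[1]]
        if (!same) break
        end_a <- g$end[cur[length(cur)]]; start_b <- g$start[nxt[1]]
        len_a <- end_a - g$start[cur[1]]
        len_b <- g$end[nxt[length(nxt)]] - start_b
        gap <- start_b - end_a
        if (gap >= max_gap_frac * (len_a + len_b)) break
        da <- apply(pm$depth[, cur, drop = FALSE], 1, stats::median)
        db <- apply(pm$depth[, nxt, drop = FALSE], 1, stats::median)
        ct <- .cor_test(da, db, p_threshold)
        # anti-correlated fragments are distinct events, never merged
        if (!ct$significant || is.na(ct$r) || ct$r <= 0) break
        cur <- c(cur, nxt)
        k <- k + 1L
        merged_any <- TRUE
      }
      out[[length(out) + 1L]] <- cur
      k <- k + 1L
    }
    members <- out
    if (!merged_any) break
  }
  .build_cnvr_set(pm, members)
}

#' Write a CNVR table and its per-sample region depths
#'
#' BED-like tab-separated `chrom, start, end, type, n_windows,
#' allele_frequency` (0-based half-open), plus an optional second file with
#' the samples x regions median depth matrix.
#'
#' @param cnvrs A `cnvr_set`.
#' @param path Output path for the region table.
#' @param depth_path Optional path for the region depth matrix.
#' @export
write_cnvr_table <- function(cnvrs, path, depth_path = NULL) {
  df <- cnvrs$calls
  lines <- c("#chrom\tstart\tend\ttype\tn_windows\tallele_frequency",
             sprintf("%s\t%d\t%d\t%s\t%d\t%.4f", df$chrom, df$start, df$end,
                     df$type, df$n_windows, df$af))
  writeLines(lines, path)
  if (!is.null(depth_path)) {
    m <- cnvrs$depth
    hdr <- paste(c("sample", sprintf("%s:%d-%d", df$chrom, df$start, df$end)),
                 collapse = "\t")
    rows <- vapply(seq_len(nrow(m)), function(i)
      paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t"),
      character(1))
    writeLines(c(hdr, rows), depth_path)
  }
  invisible(path)
}
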