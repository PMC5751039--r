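#' Count raw window read depth for one sample
#'
#' Reads a coordinate-addressable SAM/BAM file and counts, for every
#' retained grid window, the number of reads whose alignment center falls
#' inside the window (0-based half-open). Reads failing the 0x504 flag mask
#' (unmapped, secondary, PCR duplicate) are discarded; every end of a pair
#' is counted independently. The read center is
#' `floor((leftmost + rightmost aligned position) / 2)` on the reference.
#' With the half-window step, each center increments (up to) two
#' overlapping windows.
#'
#' @param alignments Path to a BAM file, or a SAM text file (converted on
#'   the fly).
#' @param grid A `window_grid` for the reference the reads were aligned to.
#' @param sample_id Sample name recorded in the profile; defaults to the
#'   file name.
#' @return A `sample_profile` with `stage = "raw"` and one depth per
#'   retained grid window.
#' @export
count_raw_depth <- function(alignments, grid, sample_id = NULL) {
  stopifnot(inherits(grid, "window_grid"))
  if (is.null(sample_id))
    sample_id <- sub("\\.(bam|sam)$", "", basename(alignments))
  bam <- alignments
  if (grepl("\\.sam$", alignments, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(alignments,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE)      # the 0x504 mask
  aln <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flag))
  if (length(aln) == 0L) stop("no usable reads in ", alignments)

  lens <- attr(grid, "seqlengths")
  step <- attr(grid, "step")
  w <- attr(grid, "window_size")
  n_pref <- .grid_prefilter_counts(grid)
  pref_offset <- c(0L, cumsum(n_pref))
  counts <- numeric(sum(n_pref))

  rn <- as.character(GenomicAlignments::seqnames(aln))
  unknown <- setdiff(unique(rn), names(lens))
  if (length(unknown)) {
    warning("skipping reads on sequences absent from the grid: ",
            paste(unknown, collapse = ", "))
  }
  # midpoint of the 0-based half-open aligned span
  center <- (BiocGenerics::start(aln) - 1L + BiocGenerics::end(aln)) %/% 2L
  si <- match(rn, names(lens))
  ok <- !is.na(si)
  center <- center[ok]; si <- si[ok]
  if (!length(center)) stop("no usable reads on grid sequences in ", alignments)

  j2 <- center %/% step
  for (cand in list(j2, j2 - 1L)) {
    valid <- cand >= 0L & cand < n_pref[si]
    if (any(valid)) {
      gidx <- pref_offset[si[valid]] + cand[valid] + 1L
      tab <- tabulate(gidx, nbins = length(counts))
      counts <- counts + tab
    }
  }
  new_sample_profile(sample_id, "raw", counts[grid$index], grid)
}

new_sample_profile <- function(sample_id, stage, depths, grid,
                               sex = "unknown") {
  stopifnot(length(depths) == nrow(grid), all(depths >= 0 | is.na(depths)))
  structure(list(sample_id = sample_id, stage = stage,
                 depths = as.numeric(depths), sex = sex,
                 window_size = attr(grid, "window_size"),
                 n_windows = nrow(grid)),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf("sample_profile '%s': %d windows (%d bp), stage=%s, sex=%s\n",
              x$sample_id, x$n_windows, x$window_size, x$stage, x$sex))
  cat(sprintf("  depth summary: min %.3g / median %.3g / mean %.3g / max %.3g\n",
              min(x$depths), stats::median(x$depths), mean(x$depths),
              max(x$depths)))
  invisible(x)
}

#' Absolute copy number correction
#'
#' Sums the raw depths of all windows linked in the duplicated-window
#' record, so depth smeared over assembly copies of a duplication is
#' restored to the locus's absolute copy number. Self-linked windows are
#' unchanged.
#'
#' @param profile A `sample_profile` at stage `"raw"`.
#' @param dup A `dup_record` aligned to the same grid.
#' @return The profile at stage `"absolute"`.
#' @export
absolute_correction <- function(profile, dup) {
  stopifnot(inherits(profile, "sample_profile"), inherits(dup, "dup_record"))
  if (profile$stage != "raw")
    stop("absolute correction applies to stage 'raw' (got '", profile$stage, "')")
  if (length(dup$links) != profile$n_windows ||
      dup$window_size != profile$window_size)
    stop("dup record does not match the profile's grid")
  nl <- lengths(dup$links)
  multi <- which(nl > 1L)
  d <- profile$depths
  if (length(multi)) {
    d[multi] <- vapply(multi, function(i) sum(profile$depths[dup$links[[i]]]),
                       numeric(1))
  }
  profile$depths <- d
  profile$stage <- "absolute"
  profile
}

#' GC bias correction
#'
#' Depths are rescaled per window by the ratio of the mean depth in the
#' 40\%-GC bin to the mean depth in the window's own GC bin (1\% bins on
#' the window GC fraction). Bins with fewer than `min_bin_windows` windows
#' borrow the nearest populated bin.
#'
#' @param profile A `sample_profile` at stage `"absolute"` (or `"raw"` when
#'   running without a duplicated-window record).
#' @param grid The matching `window_grid`.
#' @param min_bin_windows Minimum windows for a GC bin to stand on its own.
#' @param reference_gc GC percent of the reference bin (default 40).
#' @return The profile at stage `"gc_corrected"`, with the fitted model in
#'   `$gc_model` (bin means, reference-bin mean, borrowing map).
#' @export
gc_correction <- function(profile, grid, min_bin_windows = 100L,
                          reference_gc = 40L) {
  stopifnot(inherits(profile, "sample_profile"), inherits(grid, "window_grid"))
  if (!profile$stage %in% c("absolute", "raw"))
    stop("GC correction applies before sex correction and normalization ",
         "(got stage '", profile$stage, "')")
  if (profile$n_windows != nrow(grid)) stop("profile does not match grid")
  bin <- as.integer(round(grid$gc * 100))
  usable <- !is.na(bin)
  tab <- table(bin[usable])
  bins <- as.integer(names(tab))
  counts <- as.integer(tab)
  means <- vapply(bins, function(b) mean(profile$depths[usable & bin == b]),
                  numeric(1))
  populated <- bins[counts >= min_bin_windows]
  if (length(populated) == 0L)
    stop("no GC bin holds >= ", min_bin_windows,
         " windows; lower min_bin_windows or use a larger reference")
  borrow <- vapply(bins, function(b) populated[which.min(abs(populated - b))],
                   integer(1))
  eff_mean <- means[match(borrow, bins)]
  ref_bin <- populated[which.min(abs(populated - reference_gc))]
  rd_ref <- means[match(ref_bin, bins)]
  if (!is.finite(rd_ref) || rd_ref <= 0)
    stop("mean depth of the ", reference_gc,
         "% GC reference bin is not positive; choose a different reference bin")
  factor <- rep(1, profile$n_windows)
  factor[usable] <- rd_ref / eff_mean[match(bin[usable], bins)]
  factor[!is.finite(factor)] <- 1
  profile$depths <- profile$depths * factor
  profile$stage <- "gc_corrected"
  profile$gc_model <- list(bin_width = 1L, bins = bins, counts = counts,
                           mean_depth = means, borrowed_bin = borrow,
                           reference_gc = as.integer(reference_gc),
                           reference_bin_used = ref_bin,
                           rd_reference = rd_ref,
                           global_median = stats::median(profile$depths))
  profile
}

#' Sex chromosome depth correction
#'
#' If the sample's median depth on the named sex chromosome is below 0.6
#' times its median depth on the remaining placed chromosomes, the sample
#' is called heterogametic (XY/ZW) and its sex-chromosome depths are
#' doubled; otherwise it is homogametic and left unchanged. Unplaced
#' scaffolds are never corrected.
#'
#' @param profile A `sample_profile` at stage `"gc_corrected"`.
#' @param grid The matching `window_grid`.
#' @param sex_chrom Name of the X (or Z) chromosome; `NULL` or `""` skips
#'   the correction and leaves sex `"unknown"`.
#' @param placed Character vector of placed chromosome names used for the
#'   autosomal median (default: every grid sequence).
#' @param ratio_threshold Heterogametic calling threshold (default 0.6).
#' @return The profile with `sex` set and depths possibly doubled on the
#'   sex chromosome.
#' @export
sex_correction <- function(profile, grid, sex_chrom, placed = NULL,
                           ratio_threshold = 0.6) {
  stopifnot(inherits(profile, "sample_profile"), inherits(grid, "window_grid"))
  if (is.null(sex_chrom) || !nzchar(sex_chrom)) return(profile)
  chroms <- names(attr(grid, "seqlengths"))
  if (!sex_chrom %in% chroms)
    stop("sex chromosome '", sex_chrom, "' not in the grid; available: ",
         paste(chroms, collapse = ", "))
  if (is.null(placed)) placed <- chroms
  on_sex <- grid$chrom == sex_chrom
  on_auto <- grid$chrom %in% setdiff(placed, sex_chrom)
  if (!any(on_sex) || !any(on_auto)) return(profile)
  ratio <- stats::median(profile$depths[on_sex]) /
           stats::median(profile$depths[on_auto])
  if (is.finite(ratio) && ratio < ratio_threshold) {
    profile$depths[on_sex] <- profile$depths[on_sex] * 2
    profile$sex <- "heterogametic"
  } else {
    profile$sex <- "homogametic"
  }
  profile
}

#' Normalize a depth profile to median 1
#'
#' Divides every window depth by the genome-wide median so a diploid (copy
#' number 2) window sits at 1.0, making samples of different sequencing
#' depth comparable.
#'
#' @param profile A `sample_profile` at stage `"gc_corrected"` (after any
#'   sex correction).
#' @return The profile at stage `"normalized"`.
#' @export
normalize_depth <- function(profile) {
  stopifnot(inherits(profile, "sample_profile"))
  med <- stats::median(profile$depths)
  if (!is.finite(med) || med <= 0)
    stop("global median depth is not positive; cannot normalize")
  profile$depths <- profile$depths / med
  profile$stage <- "normalized"
  profile
}

#' Run the whole per-sample correction chain
#'
#' raw counts -> absolute correction -> GC correction -> sex correction ->
#' median normalization, in the order the corrections depend on each other.
#'
#' @param profile A `sample_profile` at stage `"raw"`.
#' @param grid The matching `window_grid`.
#' @param dup Optional `dup_record`; `NULL` skips absolute correction.
#' @param sex_chrom Optional sex chromosome name (see [sex_correction()]).
#' @param gc Apply GC correction (default TRUE).
#' @param min_bin_windows Passed to [gc_correction()].
#' @return A normalized `sample_profile`.
#' @export
process_sample <- function(profile, grid, dup = NULL, sex_chrom = NULL,
                           gc = TRUE, min_bin_windows = 100L) {
  if (!is.null(dup)) profile <- absolute_correction(profile, dup)
  else profile$stage <- "absolute"
  if (gc) profile <- gc_correction(profile, grid, min_bin_windows)
  else profile$stage <- "gc_corrected"
  profile <- sex_correction(profile, grid, sex_chrom)
  normalize_depth(profile)
}

#' Write / read the per-sample intermediate depth file
#'
#' The normalized profile is the reusable per-sample intermediate: once
#' written, population assembly never re-touches the alignments. Format:
#' `#` header (sample, window size, stage, sex) followed by tab-separated
#' `chrom, start, end, depth` rows, depths at full float precision.
#'
#' @param profile A `sample_profile` (normally stage `"normalized"`).
#' @param grid The matching `window_grid`.
#' @param path File path.
#' @export
write_profile <- function(profile, grid, path) {
  stopifnot(inherits(profile, "sample_profile"),
            profile$n_windows == nrow(grid))
  hdr <- c(sprintf("#sample=%s", profile$sample_id),
           sprintf("#window_size=%d", profile$window_size),
           sprintf("#stage=%s", profile$stage),
           sprintf("#sex=%s", profile$sex))
  body <- sprintf("%s\t%d\t%d\t%s", grid$chrom, grid$start, grid$end,
                  sprintf("%.17g", profile$depths))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path, grid) {
  stopifnot(inherits(grid, "window_grid"))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    h <- hdr[startsWith(hdr, paste0("#", key, "="))]
    if (length(h) != 1L) stop("profile header missing '", key, "': ", path)
    sub(paste0("^#", key, "="), "", h)
  }
  w <- as.integer(get("window_size"))
  if (w != attr(grid, "window_size"))
    stop(sprintf("profile window_size (%d) does not match grid window_size (%d)",
                 w, attr(grid, "window_size")))
  body <- lines[!startsWith(lines, "#")]
  f <- strsplit(body, "\t", fixed = TRUE)
  if (length(f) != nrow(grid))
    stop("profile has ", length(f), " windows but the grid has ", nrow(grid))
  chrom <- vapply(f, `[`, character(1), 1L)
  start <- as.integer(vapply(f, `[`, character(1), 2L))
  if (!all(chrom == grid$chrom) || !all(start == grid$start))
    stop("profile windows do not match the grid: ", path)
  depths <- as.numeric(vapply(f, `[`, character(1), 4L))
  p <- new_sample_profile(get("sample"), get("stage"), depths, grid,
                          sex = get("sex"))
  p
}
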