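#' Build an overlapping sliding-window grid over a reference genome
#'
#' Divides every sequence of the reference (chromosomes and unplaced
#' scaffolds alike) into overlapping sliding windows of `window_size` bases
#' with a step of `window_size / 2`, records the GC and gap (N) fraction of
#' each window, and drops windows with more than 50\% gap bases. Dropped
#' windows keep their place in the index space: the `index` column is the
#' pre-filter enumeration, so depth vectors and duplicated-window records
#' built against the same reference stay aligned.
#'
#' Coordinates are 0-based half-open throughout. Trailing partial windows
#' shorter than `window_size` are not emitted.
#'
#' @param reference Path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @param window_size Window width in bases; must be even and >= 2.
#' @param max_gap_frac Maximum tolerated fraction of N bases (default 0.5).
#' @return A `window_grid`: a data.frame with columns `index`, `chrom`,
#'   `start`, `end`, `gc`, `gap` and attributes `window_size`, `step`,
#'   `seqlengths`.
#' @export
build_window_grid <- function(reference, window_size, max_gap_frac = 0.5) {
  if (length(window_size) != 1L || !is.finite(window_size) || window_size < 2)
    stop("window_size must be a single value >= 2")
  window_size <- as.integer(window_size)
  if (window_size %% 2L != 0L)
    stop("window_size must be even: the step size is window_size/2 and must be integral")
  seqs <- .load_reference(reference)
  if (length(seqs) == 0L || sum(Biostrings::width(seqs)) == 0L)
    stop("reference is empty")
  step <- window_size %/% 2L
  lens <- Biostrings::width(seqs)
  names(lens) <- names(seqs)

  per_chrom <- lapply(seq_along(seqs), function(si) {
    len <- lens[[si]]
    if (len < window_size) return(NULL)
    starts <- seq.int(0L, len - window_size, by = step)
    v <- Biostrings::Views(seqs[[si]], start = starts + 1L, width = window_size)
    lf <- Biostrings::letterFrequency(v, c("A", "C", "G", "T", "N"))
    acgt <- rowSums(lf[, c("A", "C", "G", "T"), drop = FALSE])
    gc <- ifelse(acgt > 0, rowSums(lf[, c("C", "G"), drop = FALSE]) / acgt, NA_real_)
    gap <- lf[, "N"] / window_size
    data.frame(chrom = names(seqs)[si], start = starts,
               end = starts + window_size, gc = gc, gap = gap,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, per_chrom)
  if (is.null(grid) || nrow(grid) == 0L)
    stop("reference has no sequence long enough for a single window")
  grid$index <- seq_len(nrow(grid))        # pre-filter enumeration
  grid <- grid[grid$gap <= max_gap_frac, , drop = FALSE]
  if (nrow(grid) == 0L) stop("all windows were removed by the gap filter")
  grid <- grid[, c("index", "chrom", "start", "end", "gc", "gap")]
  rownames(grid) <- NULL
  structure(grid,
            window_size = window_size, step = step, seqlengths = lens,
            class = c("window_grid", "data.frame"))
}

.load_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) return(reference)
  if (!file.exists(reference)) stop("reference not found: ", reference)
  Biostrings::readDNAStringSet(reference)
}

#' GC fraction of a DNA sequence
#'
#' (G+C) / (A+C+G+T); ambiguous/N bases are excluded from the denominator.
#' Returns `NA` when no unambiguous base is present.
#'
#' @param sequence A character string or [Biostrings::DNAString].
#' @return Fraction in \[0, 1\], or `NA`.
#' @export
compute_gc <- function(sequence) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  if (length(sequence) == 0L) stop("sequence is empty")
  lf <- Biostrings::letterFrequency(sequence, c("A", "C", "G", "T"))
  denom <- sum(lf)
  if (denom == 0) return(NA_real_)
  unname((lf[["G"]] + lf[["C"]]) / denom)
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("window_grid: %d retained windows (%d-bp windows, %d-bp step) on %d sequence(s)\n",
              nrow(x), attr(x, "window_size"), attr(x, "step"),
              length(attr(x, "seqlengths"))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

# number of pre-filter windows on each sequence, in reference order
.grid_prefilter_counts <- function(grid) {
  lens <- attr(grid, "seqlengths")
  w <- attr(grid, "window_size")
  step <- attr(grid, "step")
  n <- ifelse(lens >= w, (lens - w) %/% step + 1L, 0L)
  as.integer(n)
}

#' Write / read a window grid as a tab-separated file
#'
#' The file has `#`-prefixed header lines carrying the window size, step and
#' the reference sequence lengths, then one row per retained window:
#' `index, chrom, start, end, gc, gap` (0-based half-open).
#'
#' @param grid A `window_grid`.
#' @param path Output file path.
#' @export
write_window_grid <- function(grid, path) {
  lens <- attr(grid, "seqlengths")
  hdr <- c(sprintf("#window_size=%d\tstep=%d", attr(grid, "window_size"),
                   attr(grid, "step")),
           sprintf("#seq=%s:%d", names(lens), lens))
  body <- sprintf("%d\t%s\t%d\t%d\t%s\t%s", grid$index, grid$chrom,
                  grid$start, grid$end, sprintf("%.6f", grid$gc),
                  sprintf("%.6f", grid$gap))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_window_grid
#' @export
read_window_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (length(hdr) < 2L) stop("malformed grid file: missing header")
  m <- regmatches(hdr[1], regexec("#window_size=(\\d+)\tstep=(\\d+)", hdr[1]))[[1]]
  if (length(m) != 3L) stop("malformed grid header: ", hdr[1])
  w <- as.integer(m[2]); step <- as.integer(m[3])
  seqh <- hdr[startsWith(hdr, "#seq=")]
  sm <- regmatches(seqh, regexec("#seq=(.+):(\\d+)$", seqh))
  lens <- vapply(sm, function(z) as.integer(z[3]), integer(1))
  names(lens) <- vapply(sm, function(z) z[2], character(1))
  body <- lines[!startsWith(lines, "#")]
  con <- textConnection(body)
  on.exit(close(con))
  df <- utils::read.table(con, sep = "\t", col.names =
      c("index", "chrom", "start", "end", "gc", "gap"),
      colClasses = c("integer", "character", "integer", "integer",
                     "numeric", "numeric"))
  structure(df, window_size = w, step = step, seqlengths = lens,
            class = c("window_grid", "data.frame"))
}
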