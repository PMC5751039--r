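#' Build the duplicated-window record for absolute copy number correction
#'
#' Reads from segmentally duplicated loci map ambiguously and their depth is
#' smeared over all assembly copies; summing raw depths over windows of high
#' sequence similarity recovers the absolute copy number. This function
#' links windows whose sequences align at >= `similarity_threshold` identity
#' (default 97\%).
#'
#' The search splits the reference into nonoverlapping `window_size` windows
#' and aligns each against the whole genome with an exact k-mer seed
#' (k = 16, forward strand) extended to full-window gap-free identity
#' (matches / `window_size`). Windows with more than `max_hits` similar loci
#' are treated as low-complexity and left self-linked (kept in the grid but
#' excluded from correction). The nonoverlapping links are then transferred
#' to the overlapping analysis grid by shifting each partner by the query
#' window's offset within its covering nonoverlapping window(s) and taking
#' the union.
#'
#' @param reference FASTA path or [Biostrings::DNAStringSet] (the same
#'   reference the grid was built from).
#' @param grid A `window_grid` built with the same `window_size`.
#' @param similarity_threshold Minimum full-window identity in (0, 1\].
#' @param max_hits Maximum number of similar loci before a window is
#'   considered low-complexity (default 20).
#' @param seed_spacing Distance between seed k-mers within a window.
#' @return A `dup_record`: list with `links` (one sorted integer vector of
#'   grid row positions per retained window, self always included) and the
#'   search parameters.
#' @export
build_dup_record <- function(reference, grid, similarity_threshold = 0.97,
                             max_hits = 20L, seed_spacing = 100L) {
  stopifnot(inherits(grid, "window_grid"))
  if (similarity_threshold <= 0 || similarity_threshold > 1)
    stop("similarity_threshold must be in (0, 1]")
  if (max_hits < 1L) stop("max_hits must be >= 1")
  seqs <- .load_reference(reference)
  w <- attr(grid, "window_size")
  lens <- attr(grid, "seqlengths")
  if (!identical(names(lens), names(seqs)) ||
      !all(lens == Biostrings::width(seqs)))
    stop("reference does not match the grid's sequence lengths")
  k <- 16L

  # nonoverlapping windows, enumerated per chromosome
  nover <- lapply(seq_along(seqs), function(si) {
    len <- lens[[si]]
    if (len < w) return(integer(0))
    seq.int(0L, len - w, by = w)
  })
  n_nover <- lengths(nover)
  nv_chrom <- rep.int(seq_along(seqs), n_nover)
  nv_start <- unlist(nover, use.names = FALSE)
  n_windows <- length(nv_start)
  nv_links <- vector("list", n_windows)
  for (i in seq_len(n_windows)) nv_links[[i]] <- i

  if (n_windows > 0L) {
    win_seq <- character(n_windows)
    for (si in seq_along(seqs)) {
      sel <- which(nv_chrom == si)
      if (!length(sel)) next
      v <- Biostrings::Views(seqs[[si]], start = nv_start[sel] + 1L, width = w)
      win_seq[sel] <- as.character(v)
    }

    offs <- seq.int(0L, w - k, by = as.integer(seed_spacing))
    pat <- character(0); pwin <- integer(0); poff <- integer(0)
    for (o in offs) {
      p <- substr(win_seq, o + 1L, o + k)
      keep <- !grepl("[^ACGT]", p)
      pat <- c(pat, p[keep])
      pwin <- c(pwin, which(keep))
      poff <- c(poff, rep.int(o, sum(keep)))
    }

    cand_win <- integer(0); cand_chrom <- integer(0); cand_start <- integer(0)
    if (length(pat)) {
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(pat))
      for (si in seq_along(seqs)) {
        m <- Biostrings::matchPDict(pd, seqs[[si]])
        st <- BiocGenerics::start(m)
        nh <- lengths(st)
        if (!sum(nh)) next
        qi <- rep.int(seq_along(pat), nh)
        ts <- unlist(st, use.names = FALSE) - 1L - poff[qi]
        ok <- ts >= 0L & ts + w <= lens[[si]]
        cand_win <- c(cand_win, pwin[qi][ok])
        cand_chrom <- c(cand_chrom, rep.int(si, sum(ok)))
        cand_start <- c(cand_start, ts[ok])
      }
    }

    if (length(cand_win)) {
      dup <- duplicated(paste(cand_win, cand_chrom, cand_start))
      cand_win <- cand_win[!dup]; cand_chrom <- cand_chrom[!dup]
      cand_start <- cand_start[!dup]
      is_self <- cand_chrom == nv_chrom[cand_win] &
                 cand_start == nv_start[cand_win]
      keep <- is_self
      need <- which(!is_self)
      if (length(need)) {
        qraw <- lapply(win_seq, charToRaw)
        tcache <- lapply(seqs, function(s) charToRaw(as.character(s)))
        minm <- ceiling(similarity_threshold * w)
        hit <- vapply(need, function(ci) {
          tr <- tcache[[cand_chrom[ci]]][(cand_start[ci] + 1L):(cand_start[ci] + w)]
          sum(qraw[[cand_win[ci]]] == tr) >= minm
        }, logical(1))
        keep[need] <- hit
      }
      cand_win <- cand_win[keep]; cand_chrom <- cand_chrom[keep]
      cand_start <- cand_start[keep]

      # assign each hit to the nonoverlapping window containing its midpoint
      nv_offset <- c(0L, cumsum(n_nover))[seq_along(seqs)]
      part_local <- pmin((cand_start + w %/% 2L) %/% w,
                         pmax(n_nover[cand_chrom] - 1L, 0L))
      partner <- nv_offset[cand_chrom] + part_local + 1L
      for (i in unique(cand_win)) {
        p <- sort(unique(c(i, partner[cand_win == i])))
        nv_links[[i]] <- if (length(p) > max_hits) i else p
      }
    }
  }

  # transfer to the overlapping grid: shift each partner by the query's
  # offset inside its covering nonoverlapping window(s), union the lists
  step <- attr(grid, "step")
  n_pref <- .grid_prefilter_counts(grid)
  pref_offset <- c(0L, cumsum(n_pref))
  nv_offset <- c(0L, cumsum(n_nover))
  chrom_of <- match(grid$chrom, names(lens))
  row_of_prefilter <- integer(sum(n_pref))
  row_of_prefilter[grid$index] <- seq_len(nrow(grid))

  links <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    si <- chrom_of[r]; s <- grid$start[r]
    ks <- unique(c(s %/% w, (s + w - 1L) %/% w))
    ks <- ks[ks < n_nover[si]]
    out <- r
    for (kk in ks) {
      rel <- s - kk * w                      # 0 or step
      for (p in nv_links[[nv_offset[si] + kk + 1L]]) {
        psi <- nv_chrom[p]
        pstart <- nv_start[p] + rel
        if (pstart %% step != 0L) next
        pl <- pstart %/% step
        if (pl < 0L || pl >= n_pref[psi]) next
        prow <- row_of_prefilter[pref_offset[psi] + pl + 1L]
        if (prow > 0L) out <- c(out, prow)
      }
    }
    links[[r]] <- sort(unique(out))
  }

  structure(list(links = links, window_size = w,
                 similarity_threshold = similarity_threshold,
                 max_hits = as.integer(max_hits),
                 grid_index = grid$index),
            class = "dup_record")
}

#' @export
print.dup_record <- function(x, ...) {
  nl <- lengths(x$links)
  cat(sprintf(
    "dup_record: %d windows (%d-bp), identity >= %.2f, max %d hits; %d window(s) with partners (max group size %d)\n",
    length(x$links), x$window_size, x$similarity_threshold, x$max_hits,
    sum(nl > 1L), max(nl)))
  invisible(x)
}

#' Save / load a duplicated-window record file
#'
#' One line per retained window: the window's pre-filter grid index, a tab,
#' then the semicolon-separated pre-filter indices of its partners (self
#' included). A `#` header carries window size, similarity threshold and
#' max hits. Windows absent from the file load as self-linked.
#'
#' @param record A `dup_record`.
#' @param path File path.
#' @param grid The `window_grid` the record belongs to; the loader validates
#'   window size and indices against it.
#' @export
save_dup_record <- function(record, path) {
  hdr <- sprintf("#window_size=%d\tthreshold=%g\tmax_hits=%d",
                 record$window_size, record$similarity_threshold,
                 record$max_hits)
  idx <- record$grid_index
  body <- vapply(seq_along(record$links), function(r)
    sprintf("%d\t%s", idx[r], paste(idx[record$links[[r]]], collapse = ";")),
    character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname save_dup_record
#' @export
load_dup_record <- function(path, grid) {
  stopifnot(inherits(grid, "window_grid"))
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1], "#"))
    stop("malformed record file: missing '#' header")
  m <- regmatches(lines[1], regexec(
    "#window_size=(\\d+)\tthreshold=([0-9.eE+-]+)\tmax_hits=(\\d+)", lines[1]))[[1]]
  if (length(m) != 4L) stop("malformed record header (line 1): ", lines[1])
  w <- as.integer(m[2])
  if (w != attr(grid, "window_size"))
    stop(sprintf("record window_size (%d) does not match grid window_size (%d)",
                 w, attr(grid, "window_size")))
  row_of <- integer(max(grid$index))
  row_of[grid$index] <- seq_len(nrow(grid))
  links <- as.list(seq_len(nrow(grid)))
  body <- lines[-1]
  body <- body[nzchar(body)]
  for (ln in seq_along(body)) {
    f <- strsplit(body[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != 2L)
      stop(sprintf("malformed record line %d: %s", ln + 1L, body[ln]))
    i <- suppressWarnings(as.integer(f[1]))
    js <- suppressWarnings(as.integer(strsplit(f[2], ";", fixed = TRUE)[[1]]))
    if (is.na(i) || anyNA(js))
      stop(sprintf("malformed record line %d: %s", ln + 1L, body[ln]))
    bad <- c(i, js)[c(i, js) < 1L | c(i, js) > length(row_of)]
    if (length(bad) == 0L) bad <- c(i, js)[row_of[c(i, js)] == 0L]
    if (length(bad))
      stop(sprintf("record line %d references window index %d absent from the grid",
                   ln + 1L, bad[1]))
    links[[row_of[i]]] <- sort(unique(c(row_of[i], row_of[js])))
  }
  structure(list(links = links, window_size = w,
                 similarity_threshold = as.numeric(m[3]),
                 max_hits = as.integer(m[4]),
                 grid_index = grid$index),
            class = "dup_record")
}
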