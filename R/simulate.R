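#' Simulate a reference genome with planted copy number events
#'
#' Generates an i.i.d. random DNA sequence and plants nonoverlapping
#' events with known truth:
#' \describe{
#'   \item{assembled_SD}{a donor region duplicated in tandem, so the
#'     reference carries two identical copies and multi-mapping smears
#'     read depth across them (exercises absolute correction);}
#'   \item{collapsed_SD}{a region kept single-copy in the reference but
#'     recorded as duplicated in every individual's genome, so all copies'
#'     reads pile onto one locus;}
#'   \item{deletion / duplication}{polymorphic CNVs segregating at a given
#'     allele frequency, for population CNVR discovery.}
#' }
#' Optionally inserts N-gap runs and appends a sex chromosome whose
#' per-individual copy number follows assigned sex.
#'
#' @param length Source sequence length in bases.
#' @param n_sd Number of segmental duplication events.
#' @param sd_length Length of each SD donor region (default 5000).
#' @param sd_kinds Kinds drawn for SD events (recycled over events).
#' @param n_deletion,n_duplication Number of polymorphic CNV events.
#' @param cnv_length Length of each polymorphic event (default 5000).
#' @param cnv_af Allele frequency for polymorphic events (recycled).
#' @param gap_config Optional `list(n, length)`: N-runs overwritten into
#'   event-free sequence.
#' @param sex_chrom_length If > 0, append a sex chromosome `"X"` of this
#'   length.
#' @param chrom_name Name of the main chromosome (default `"chr1"`).
#' @param seed Integer seed; the simulation is fully deterministic.
#' @return A `cnv_simulation`: list with `reference`
#'   ([Biostrings::DNAStringSet]) and `events` (data.frame `chrom`,
#'   `start`, `end`, `kind`, `af`, final 0-based half-open coordinates;
#'   assembled_SD events span both tandem copies).
#' @export
simulate_reference <- function(length = 5e6, n_sd = 20L, sd_length = 5000L,
                               sd_kinds = c("assembled_SD", "collapsed_SD"),
                               n_deletion = 0L, n_duplication = 0L,
                               cnv_length = 5000L, cnv_af = 0.2,
                               gap_config = NULL, sex_chrom_length = 0L,
                               chrom_name = "chr1", seed = 1L) {
  set.seed(as.integer(seed))
  length <- as.integer(length)
  n_events <- n_sd + n_deletion + n_duplication
  kinds <- c(rep_len(sd_kinds, length.out = if (n_sd > 0) n_sd else 0),
             rep("deletion", n_deletion), rep("duplication", n_duplication))
  ev_len <- c(rep(as.integer(sd_length), n_sd),
              rep(as.integer(cnv_length), n_deletion + n_duplication))
  margin <- 10000L
  if (n_events > 0 && sum(ev_len) + (n_events + 1L) * margin > length)
    stop("events do not fit into the requested length; enlarge `length`")

  base <- sample(c("A", "C", "G", "T"), length, replace = TRUE)

  starts <- integer(0)
  if (n_events > 0) {
    # place events left to right with random gaps; guarantees nonoverlap
    slack <- length - sum(ev_len) - (n_events + 1L) * margin
    cuts <- sort(sample.int(slack, n_events))
    gaps <- diff(c(0L, cuts))
    starts <- margin + cumsum(gaps + c(0L, ev_len[-n_events] + margin))
    ord <- sample.int(n_events)           # random kind-to-position pairing
    kinds <- kinds[ord]; ev_len <- ev_len[ord]
    af <- ifelse(kinds %in% c("deletion", "duplication"),
                 rep_len(cnv_af, n_events), NA_real_)
  } else af <- numeric(0)

  # build the final sequence, inserting tandem copies for assembled SDs
  pieces <- character(0)
  final_start <- integer(n_events)
  final_end <- integer(n_events)
  cursor <- 1L; shift <- 0L
  for (i in seq_len(n_events)) {
    s <- starts[i]; e <- s + ev_len[i]
    pieces <- c(pieces, paste(base[cursor:e], collapse = ""))
    if (kinds[i] == "assembled_SD") {
      pieces <- c(pieces, paste(base[(s + 1L):e], collapse = ""))
      final_start[i] <- s + shift
      final_end[i] <- e + shift + ev_len[i]
      shift <- shift + ev_len[i]
    } else {
      final_start[i] <- s + shift
      final_end[i] <- e + shift
    }
    cursor <- e + 1L
  }
  pieces <- c(pieces, paste(base[cursor:length], collapse = ""))
  seq_main <- paste(pieces, collapse = "")

  events <- data.frame(chrom = rep(chrom_name, n_events),
                       start = final_start, end = final_end,
                       kind = kinds, af = af, stringsAsFactors = FALSE)

  if (!is.null(gap_config) && gap_config$n > 0) {
    gl <- as.integer(gap_config$length)
    total <- nchar(seq_main)
    placed <- 0L; tries <- 0L
    gap_starts <- integer(0)
    while (placed < gap_config$n && tries < 1000L) {
      tries <- tries + 1L
      gs <- sample.int(total - gl, 1L)
      clash <- any(events$start < gs + gl & events$end > gs - gl) ||
               any(gap_starts < gs + 2L * gl & gap_starts > gs - 2L * gl)
      if (clash) next
      substr(seq_main, gs + 1L, gs + gl) <- paste(rep("N", gl), collapse = "")
      gap_starts <- c(gap_starts, gs)
      placed <- placed + 1L
    }
  }

  seqs <- c(seq_main)
  names(seqs) <- chrom_name
  if (sex_chrom_length > 0) {
    seqs <- c(seqs, paste(sample(c("A", "C", "G", "T"),
                                 as.integer(sex_chrom_length),
                                 replace = TRUE), collapse = ""))
    names(seqs)[2] <- "X"
  }
  structure(list(reference = Biostrings::DNAStringSet(seqs),
                 events = events, seed = as.integer(seed),
                 sex_chrom = if (sex_chrom_length > 0) "X" else NULL),
            class = "cnv_simulation")
}

#' @export
print.cnv_simulation <- function(x, ...) {
  cat(sprintf("cnv_simulation: %d sequence(s), %s bases, %d event(s)\n",
              length(x$reference),
              format(sum(Biostrings::width(x$reference)), big.mark = ","),
              nrow(x$events)))
  if (nrow(x$events)) print(table(x$events$kind))
  invisible(x)
}

#' Assign per-individual diploid copy numbers for every simulated event
#'
#' Polymorphic deletions/duplications are sampled under Hardy-Weinberg
#' equilibrium at the event's allele frequency (one copy lost/gained per
#' alternative allele). SD events get a copy number drawn uniformly from
#' `sd_cn_range` per individual (direct assignment). If the simulation has
#' a sex chromosome, individuals are assigned a sex (1:1) that sets their
#' sex-chromosome copy number to 1 or 2.
#'
#' @param sim A `cnv_simulation`.
#' @param n_individuals Number of individuals.
#' @param hwe Sample polymorphic events under Hardy-Weinberg (default
#'   TRUE); otherwise all individuals are heterozygous with probability
#'   equal to the allele frequency (single-copy change).
#' @param sd_cn_range Integer copy numbers available to SD events
#'   (default 2:6).
#' @param seed Integer seed.
#' @return List with `cn` (events x individuals integer matrix), `sex`
#'   (per individual, `"homogametic"`/`"heterogametic"`), `sample_ids`.
#' @export
simulate_population <- function(sim, n_individuals, hwe = TRUE,
                                sd_cn_range = 2:6, seed = 1L) {
  stopifnot(inherits(sim, "cnv_simulation"))
  set.seed(as.integer(seed))
  ev <- sim$events
  ids <- sprintf("S%03d", seq_len(n_individuals))
  cn <- matrix(2L, nrow(ev), n_individuals,
               dimnames = list(NULL, ids))
  for (i in seq_len(nrow(ev))) {
    if (ev$kind[i] %in% c("deletion", "duplication")) {
      n_alt <- if (hwe) stats::rbinom(n_individuals, 2L, ev$af[i])
               else as.integer(stats::runif(n_individuals) < ev$af[i])
      cn[i, ] <- if (ev$kind[i] == "deletion") 2L - n_alt else 2L + n_alt
    } else {
      cn[i, ] <- sample(sd_cn_range, n_individuals, replace = TRUE)
    }
  }
  sex <- rep("homogametic", n_individuals)
  if (!is.null(sim$sex_chrom))
    sex <- ifelse(stats::runif(n_individuals) < 0.5, "heterogametic",
                  "homogametic")
  list(cn = cn, sex = sex, sample_ids = ids)
}

#' Simulate per-individual raw window counts (and optional SAM alignments)
#'
#' Draws Poisson read counts per half-window bin at rate
#' `coverage / read_length * step * m(bin)` and sums adjacent bins into the
#' overlapping windows, so overlapping windows share signal exactly as
#' read-center counting would. The local multiplier `m` is `CN/2` inside
#' deletions, duplications and collapsed SDs, `CN/4` across both copies of
#' an assembled SD (multi-mapping smears the reads uniformly over the two
#' assembly copies), `sex CN/2` on the sex chromosome, and 0 over N-gaps.
#' An optional GC bias multiplies the rate by `gc_bias(gc)` per bin.
#'
#' With `sam_dir` set, read centers are drawn uniformly within each bin
#' and minimal single-end SAM files are written whose
#' [count_raw_depth()] counts follow the same model.
#'
#' @param sim A `cnv_simulation`.
#' @param pop Output of [simulate_population()].
#' @param grid A `window_grid` built on `sim$reference`.
#' @param coverage Fold coverage of copy number 2 regions (default 20).
#' @param read_length Read length in bases (default 100).
#' @param gc_bias Optional function of GC fraction returning a multiplier.
#' @param seed Integer seed.
#' @param sam_dir If non-NULL, write one SAM file per individual here.
#' @return List of raw `sample_profile`s (and `sam_paths` when written).
#' @export
simulate_counts <- function(sim, pop, grid, coverage = 20, read_length = 100L,
                            gc_bias = NULL, seed = 1L, sam_dir = NULL) {
  stopifnot(inherits(sim, "cnv_simulation"), inherits(grid, "window_grid"))
  set.seed(as.integer(seed))
  step <- attr(grid, "step")
  w <- attr(grid, "window_size")
  lens <- attr(grid, "seqlengths")
  base_rate <- coverage / read_length * step
  n_ind <- length(pop$sample_ids)
  ev <- sim$events

  # per-chromosome bin scaffolding shared by all individuals
  bins <- lapply(seq_along(lens), function(si) {
    nb <- lens[[si]] %/% step
    if (nb < 2L) return(NULL)
    bs <- (seq_len(nb) - 1L) * step
    gc_mult <- rep(1, nb)
    gap0 <- rep(FALSE, nb)
    sq <- sim$reference[[names(lens)[si]]]
    v <- Biostrings::Views(sq, start = bs + 1L, width = step)
    lf <- Biostrings::letterFrequency(v, c("C", "G", "N", "A", "T"))
    acgt <- rowSums(lf[, c("A", "C", "G", "T"), drop = FALSE])
    gap0 <- lf[, "N"] / step > 0.5
    if (!is.null(gc_bias)) {
      gcfrac <- ifelse(acgt > 0, rowSums(lf[, c("C", "G"), drop = FALSE]) / acgt, 0.5)
      gc_mult <- gc_bias(gcfrac)
    }
    list(start = bs, gc_mult = gc_mult, gap = gap0)
  })

  profiles <- vector("list", n_ind)
  sam_paths <- character(0)
  n_pref <- .grid_prefilter_counts(grid)
  pref_offset <- c(0L, cumsum(n_pref))

  for (ind in seq_len(n_ind)) {
    counts <- numeric(sum(n_pref))
    sam_lines <- character(0)
    for (si in seq_along(lens)) {
      b <- bins[[si]]
      if (is.null(b)) next
      chrom <- names(lens)[si]
      mult <- rep(1, length(b$start))
      if (!is.null(sim$sex_chrom) && chrom == sim$sex_chrom)
        mult[] <- if (pop$sex[ind] == "heterogametic") 0.5 else 1
      evc <- ev[ev$chrom == chrom, , drop = FALSE]
      for (j in seq_len(nrow(evc))) {
        cnv <- pop$cn[which(ev$chrom == chrom)[j], ind]
        m <- if (evc$kind[j] == "assembled_SD") cnv / 4 else cnv / 2
        # overlap-weighted multiplier for bins the event partially covers
        ov_s <- pmax(b$start, evc$start[j])
        ov_e <- pmin(b$start + step, evc$end[j])
        frac <- pmax(0, ov_e - ov_s) / step
        mult <- mult * (1 + (m - 1) * frac)
      }
      rate <- base_rate * mult * b$gc_mult
      rate[b$gap] <- 0
      c_b <- stats::rpois(length(rate), rate)
      # window count = sum of its two covering bins
      nwin <- n_pref[si]
      if (nwin > 0L) {
        wc <- c_b[seq_len(nwin)] + c_b[seq_len(nwin) + 1L]
        counts[pref_offset[si] + seq_len(nwin)] <- wc
      }
      if (!is.null(sam_dir) && any(c_b > 0)) {
        centers <- unlist(lapply(which(c_b > 0), function(bi)
          b$start[bi] + sample.int(step, c_b[bi], replace = TRUE) - 1L))
        # placed so that floor((start+end)/2) lands back on the drawn center
        pos <- centers - read_length %/% 2L
        pos <- pmax(0L, pmin(pos, lens[[si]] - read_length))
        pos <- sort(pos)
        sam_lines <- c(sam_lines, sprintf(
          "r%s_%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
          chrom, seq_along(pos), chrom, pos + 1L, read_length))
      }
    }
    prof <- new_sample_profile(pop$sample_ids[ind], "raw",
                               counts[grid$index], grid)
    profiles[[ind]] <- prof
    if (!is.null(sam_dir)) {
      dir.create(sam_dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(sam_dir, paste0(pop$sample_ids[ind], ".sam"))
      hdr <- c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
      writeLines(c(hdr, sam_lines), path)
      sam_paths <- c(sam_paths, path)
    }
  }
  names(profiles) <- pop$sample_ids
  out <- list(profiles = profiles)
  if (!is.null(sam_dir)) out$sam_paths <- sam_paths
  out
}

#' Simulate trio genotypes for biallelic events
#'
#' Parents are drawn under Hardy-Weinberg at each event's allele frequency;
#' each child inherits one allele from each parent, so the truth set is
#' Mendelian-consistent by construction.
#'
#' @param sim A `cnv_simulation` whose events are all deletions or
#'   duplications.
#' @param n_trios Number of father/mother/child trios.
#' @param seed Integer seed.
#' @return List with `cn` (events x individuals), `pedigree` (data.frame
#'   `family`, `child`, `father`, `mother`), `sample_ids`, and `alt`
#'   (events x individuals alternative allele counts).
#' @export
simulate_trios <- function(sim, n_trios, seed = 1L) {
  stopifnot(inherits(sim, "cnv_simulation"))
  ev <- sim$events
  if (any(!ev$kind %in% c("deletion", "duplication")))
    stop("trio simulation needs biallelic events only (deletion/duplication)")
  set.seed(as.integer(seed))
  fam <- sprintf("fam%02d", seq_len(n_trios))
  ids <- c(rbind(paste0(fam, "_fa"), paste0(fam, "_mo"), paste0(fam, "_ch")))
  n_ev <- nrow(ev)
  alt <- matrix(0L, n_ev, 3L * n_trios, dimnames = list(NULL, ids))
  for (i in seq_len(n_ev)) {
    fa1 <- stats::rbinom(n_trios, 1L, ev$af[i])
    fa2 <- stats::rbinom(n_trios, 1L, ev$af[i])
    mo1 <- stats::rbinom(n_trios, 1L, ev$af[i])
    mo2 <- stats::rbinom(n_trios, 1L, ev$af[i])
    from_fa <- ifelse(stats::runif(n_trios) < 0.5, fa1, fa2)
    from_mo <- ifelse(stats::runif(n_trios) < 0.5, mo1, mo2)
    alt[i, ] <- c(rbind(fa1 + fa2, mo1 + mo2, from_fa + from_mo))
  }
  sgn <- ifelse(ev$kind == "deletion", -1L, 1L)
  cn <- 2L + sweep(alt, 1L, sgn, `*`)
  pedigree <- data.frame(family = fam, child = paste0(fam, "_ch"),
                         father = paste0(fam, "_fa"),
                         mother = paste0(fam, "_mo"),
                         stringsAsFactors = FALSE)
  list(cn = cn, alt = alt, pedigree = pedigree, sample_ids = ids,
       sex = rep("homogametic", length(ids)))
}

#' Write simulation truth as tab-separated files
#'
#' `events.tsv` (chrom, start, end, kind, af) and `genotypes.tsv`
#' (one row per event, one column per individual).
#'
#' @param sim A `cnv_simulation`.
#' @param pop Output of [simulate_population()] or [simulate_trios()].
#' @param dir Output directory (created).
#' @export
write_truth <- function(sim, pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- sim$events
  writeLines(c("#chrom\tstart\tend\tkind\taf",
               sprintf("%s\t%d\t%d\t%s\t%s", ev$chrom, ev$start, ev$end,
                       ev$kind, ifelse(is.na(ev$af), ".", sprintf("%.4f", ev$af)))),
             file.path(dir, "events.tsv"))
  cn <- pop$cn
  writeLines(c(paste(c("#event", colnames(cn)), collapse = "\t"),
               vapply(seq_len(nrow(cn)), function(i)
                 paste(c(i, cn[i, ]), collapse = "\t"), character(1))),
             file.path(dir, "genotypes.tsv"))
  invisible(dir)
}
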