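# Shared fixture builders; everything is generated in code at test time.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

as_ref <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

# a clean single-chromosome grid: n contiguous retained windows, no gaps
make_grid <- function(n_windows, window = 800L, gc = 0.4) {
  step <- window %/% 2L
  start <- (seq_len(n_windows) - 1L) * step
  lens <- c(chr1 = (n_windows + 1L) * step)
  structure(data.frame(index = seq_len(n_windows), chrom = "chr1",
                       start = start, end = start + window,
                       gc = rep_len(gc, n_windows), gap = 0,
                       stringsAsFactors = FALSE),
            window_size = window, step = step, seqlengths = lens,
            class = c("window_grid", "data.frame"))
}

make_profile <- function(depths, grid, id = "S1", stage = "normalized") {
  cnvpop:::new_sample_profile(id, stage, depths, grid)
}

# population matrix straight from a depth matrix (samples x windows)
make_pm <- function(depth, grid, mode = "outbred") {
  ids <- sprintf("S%02d", seq_len(nrow(depth)))
  profiles <- lapply(seq_len(nrow(depth)), function(i)
    make_profile(depth[i, ], grid, id = ids[i]))
  pm <- assemble_matrix(profiles, grid)
  flag_individual_candidates(pm, mode)
}

# minimal cnvr_set for genotyping / VCF tests
make_cnvr_set <- function(calls, depth, members = NULL) {
  if (is.null(members))
    members <- lapply(seq_len(nrow(calls)), function(k) k)
  structure(list(calls = calls, members = members, depth = depth,
                 sample_ids = rownames(depth)),
            class = "cnvr_set")
}

# hand-rolled SAM writer for counting tests
write_test_sam <- function(path, seqlens, reads) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), seqlens))
  body <- vapply(reads, function(r)
    sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
            r$name, r$flag, r$chrom, r$pos, r$cigar), character(1))
  writeLines(c(hdr, body), path)
  path
}

# a pre-baked genotyping result for VCF/evaluation tests
make_geno_result <- function(cn_int, sil = 0.9) {
  structure(list(cn_est = as.numeric(cn_int), cn_int = as.integer(cn_int),
                 assignment = rep(1L, length(cn_int)),
                 means = sort(unique(as.numeric(cn_int))),
                 sds = 0.05, weights = 1,
                 n_components = length(unique(cn_int)),
                 silhouette = sil, quality = "multi-cluster"),
            class = "cnv_genotype")
}
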