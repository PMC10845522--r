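# Shared fixture builders. Everything is generated in code under fixed seeds.

suppressMessages({
  library(dplyr)
  library(tibble)
})

# a plain unmasked single-chromosome genome as DNAStringSet
flat_genome <- function(len = 5000, name = "chr1", seed = 1) {
  withr::with_seed(seed, {
    Biostrings::DNAStringSet(stats::setNames(
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      name
    ))
  })
}

empty_mask <- function() tibble(chrom = character(), start = integer(), end = integer())

# hand-built window profile: one chromosome, contiguous 1-kb windows with the
# given per-window CN values
profile_from_cn <- function(cn, chrom = "chr1", span = 1000L) {
  n <- length(cn)
  tibble(
    chrom = chrom,
    start = (seq_len(n) - 1L) * span,
    end = seq_len(n) * span,
    unmasked = span,
    cn = cn
  )
}

# tandem array from a fresh random monomer: n diverged copies, concatenated
make_array <- function(monomer_length, n_copies, divergence = 0.02,
                       at_fraction = 0.6, seed = 1) {
  withr::with_seed(seed, {
    monomer <- vitiscan:::random_dna(monomer_length, gc = 1 - at_fraction)
    copies <- vapply(seq_len(n_copies),
                     function(i) vitiscan:::mutate_seq(monomer, divergence),
                     character(1))
    list(monomer = monomer, array = paste(copies, collapse = ""))
  })
}

# independent per-base windowing oracle: scan left to right, close a window at
# every w-th unmasked base, drop the remainder
oracle_windows <- function(masked, w) {
  starts <- integer(0); ends <- integer(0)
  acc <- 0L; cur_start <- NA_integer_
  for (p in seq_along(masked)) {
    if (masked[p]) next
    if (acc == 0L) cur_start <- p
    acc <- acc + 1L
    if (acc == w) {
      starts <- c(starts, cur_start - 1L)
      ends <- c(ends, p)
      acc <- 0L
    }
  }
  tibble(start = starts, end = ends)
}

# brute-force per-base intersection oracle over a toy genome
oracle_shared <- function(regions, genome_len) {
  samples <- unique(regions$sample_id)
  cover <- rep(TRUE, genome_len)
  for (s in samples) {
    v <- rep(FALSE, genome_len)
    rs <- regions[regions$sample_id == s, ]
    for (i in seq_len(nrow(rs))) {
      if (rs$end[i] > rs$start[i]) v[(rs$start[i] + 1L):rs$end[i]] <- TRUE
    }
    cover <- cover & v
  }
  r <- rle(cover)
  e <- cumsum(r$lengths)
  s0 <- e - r$lengths
  tibble(start = s0[r$values], end = e[r$values])
}
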