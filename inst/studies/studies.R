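# Reproducibility studies: each function runs one property-based evaluation of
# the package on synthetic data with known ground truth and returns the
# measured quantities. Shared by the test suite and scripts/acceptance.R.
# All functions take a base seed and are deterministic given it.

suppressMessages({
  library(vitiscan)
  library(dplyr)
  library(tibble)
})

# --- WSSD / digital-CGH recovery on a 1-Mb genome ---------------------------
# 20-kb CN=4 duplication and 15-kb CN=1 deletion at 30x; one row per seed with
# per-caller recovery (boundary error <= 2 windows) and false-call counts.
study_sv_recovery <- function(n_seeds = 20, seed = 1, coverage = 30) {
  dup <- c(300000L, 320000L); del <- c(600000L, 615000L)
  ev <- bind_rows(
    tibble(sample_id = "S", chrom = "chr1", start = dup[1], end = dup[2],
           kind = "duplication", cn = 4),
    tibble(sample_id = "S", chrom = "chr1", start = del[1], end = del[2],
           kind = "deletion", cn = 1)
  )
  near <- function(calls, kind, bounds, tol = 2000L) {
    k <- calls[calls$kind == kind, ]
    nrow(k) == 1 && abs(k$start - bounds[1]) <= tol && abs(k$end - bounds[2]) <= tol
  }
  rows <- lapply(seq_len(n_seeds), function(i) {
    s <- seed + i * 13L
    sim <- sim_reference(c(chr1 = 1000000), events = ev, seed = s)
    win <- define_windows(sim)
    rs <- sim_read_starts(derive_sample(sim, "S"), coverage = coverage,
                          read_length = 100, seed = s + 1L)
    prof <- calibrate_cn(window_depth(win, rs, read_length = 100))
    wssd <- call_wssd(prof)
    flat <- tibble(chrom = "chr1", start = 0L, end = 1000000L, cn = 2)
    rs_ref <- sim_read_starts(flat, coverage = coverage, read_length = 100,
                              seed = s + 2L)
    ref <- calibrate_cn(window_depth(win, rs_ref, read_length = 100))
    cgh <- call_cgh(compute_l2r(prof, ref))
    hits_truth <- function(calls, kinds) {
      calls$kind == kinds[1] & calls$start < dup[2] & dup[1] < calls$end |
        calls$kind == kinds[2] & calls$start < del[2] & del[1] < calls$end
    }
    tibble(
      seed = s,
      wssd_ok = near(wssd, "duplication", dup) && near(wssd, "deletion", del),
      wssd_false = sum(!hits_truth(wssd, c("duplication", "deletion"))),
      cgh_ok = near(cgh, "gain", dup) && near(cgh, "loss", del),
      cgh_false = sum(!hits_truth(cgh, c("gain", "loss")))
    )
  })
  bind_rows(rows)
}

# --- digital-CGH null and antisymmetry --------------------------------------
study_cgh_null <- function(seed = 1) {
  sim <- sim_reference(c(chr1 = 400000), samples = "S", seed = seed)
  win <- define_windows(sim)
  mk <- function(s) calibrate_cn(window_depth(
    win, sim_read_starts(derive_sample(sim, "S"), coverage = 30,
                         read_length = 100, seed = s), read_length = 100))
  a <- mk(seed + 1L); b <- mk(seed + 2L)
  self_regions <- nrow(call_cgh(compute_l2r(a, a)))
  ab <- compute_l2r(a, b); ba <- compute_l2r(b, a)
  asym <- max(abs(ab$l2r + ba$l2r), na.rm = TRUE)
  gains_ab <- call_cgh(ab); gains_ab <- gains_ab[gains_ab$kind == "gain", ]
  losses_ba <- call_cgh(ba); losses_ba <- losses_ba[losses_ba$kind == "loss", ]
  swap_exact <- identical(gains_ab[, c("chrom", "start", "end", "n_windows")],
                          losses_ba[, c("chrom", "start", "end", "n_windows")])
  list(self_regions = self_regions, l2r_asymmetry = asym,
       swap_exact = as.integer(swap_exact))
}

# --- shared-CNVR intersection vs per-base boolean-AND oracle ----------------
study_cnvr_oracle <- function(n_cases = 50, seed = 1, genome_len = 100000L) {
  oracle <- function(regions) {
    cover <- rep(TRUE, genome_len)
    for (s in unique(regions$sample_id)) {
      v <- rep(FALSE, genome_len)
      rs <- regions[regions$sample_id == s, ]
      for (i in seq_len(nrow(rs))) v[(rs$start[i] + 1L):rs$end[i]] <- TRUE
      cover <- cover & v
    }
    r <- rle(cover); e <- cumsum(r$lengths); s0 <- e - r$lengths
    tibble(start = s0[r$values], end = e[r$values])
  }
  agree <- vapply(seq_len(n_cases), function(i) {
    regions <- withr::with_seed(seed + i, {
      n_samp <- sample(2:4, 1)
      bind_rows(lapply(seq_len(n_samp), function(s) {
        n_reg <- sample(1:8, 1)
        starts <- sort(sample.int(genome_len - 10000L, n_reg))
        tibble(sample_id = paste0("S", s), chrom = "chr1", start = starts,
               end = pmin(starts + sample(200:9000, n_reg, replace = TRUE),
                          genome_len),
               kind = "gain")
      }))
    })
    shared <- intersect_cnvrs(regions)
    shared <- shared[shared$status == "shared", ]
    ora <- oracle(regions)
    identical(as.integer(shared$start), as.integer(ora$start)) &&
      identical(as.integer(shared$end), as.integer(ora$end))
  }, logical(1))
  mean(agree)
}

# --- chi-square exactness and type-I calibration ----------------------------
study_chisq <- function(n_tables = 100, n_sims = 2000, seed = 1) {
  max_err <- 0
  for (i in seq_len(n_tables)) {
    tbl <- withr::with_seed(seed + i, {
      k <- sample(3:19, 1)
      tibble(chrom = paste0("c", 1:k), length = sample(1e5:5e6, k),
             observed = as.integer(rmultinom(1, 800, runif(k, 0.5, 2))))
    })
    x <- chisq_randomness(tbl)
    rate <- sum(tbl$observed) / sum(tbl$length / 1000)
    acc <- 0
    for (j in seq_len(nrow(tbl))) {
      e <- rate * tbl$length[j] / 1000
      acc <- acc + (tbl$observed[j] - e)^2 / e
    }
    max_err <- max(max_err, abs(x$statistic - acc))
  }
  # type-I error under a length-proportional multinomial null (19 chromosomes)
  lens <- withr::with_seed(seed, sample(5e6:3e7, 19))
  probs <- lens / sum(lens)
  base <- tibble(chrom = paste0("chr", 1:19), length = lens)
  rejections <- withr::with_seed(seed + 999, {
    vapply(seq_len(n_sims), function(i) {
      base$observed <- as.integer(rmultinom(1, 1000, probs))
      chisq_randomness(base)$p_value <= 0.05
    }, logical(1))
  })
  list(max_stat_error = max_err, type1_rate = mean(rejections), n_sims = n_sims)
}

# --- repeat genome-proportion recovery at 250k standardized reads -----------
study_repeat_recovery <- function(seed = 1, n_raw_reads = 300000,
                                  final_reads = 250000) {
  ev <- bind_rows(
    tibble(kind = "satellite_array", chrom = "chr1", start = 1000000L,
           monomer_length = 107L, n_copies = 9346L, divergence = 0.02,
           family_id = "satA"),
    tibble(kind = "dispersed_family", family_id = "famB",
           element_length = 3000L, proportion = 0.05, divergence = 0.03),
    tibble(kind = "dispersed_family", family_id = "famC",
           element_length = 5000L, proportion = 0.10, divergence = 0.03)
  )
  sim <- sim_reference(stats::setNames(rep(5e6, 10), paste0("chr", 1:10)),
                       events = ev, seed = seed)
  raw <- sim_reads(sim, n_reads = n_raw_reads, read_length = 110,
                   error_rate = 0.005, low_q_tail_frac = 0.1, seed = seed + 1L)
  prep <- prepare_reads(raw, n_sample = 1e6, seed = 100, final_n = final_reads)
  cl <- cluster_reads(prep)
  lab <- classify_clusters(cl, prep, dplyr::rename(sim$families, family = family_id))
  genome_len <- sum(sim$chrom_lengths$length)
  truth <- sim$truth |>
    group_by(family_id) |>
    summarise(true_prop = sum(end - start) / genome_len, .groups = "drop")
  est <- lab |>
    as_tibble() |>
    group_by(family_id = .data$label) |>
    summarise(est_prop = sum(proportion), .groups = "drop")
  left_join(truth, est, by = "family_id") |>
    mutate(est_prop = ifelse(is.na(est_prop), 0, est_prop),
           rel_error = abs(est_prop - true_prop) / true_prop)
}

# --- Wilcoxon per-family false-flag rate under an identical-groups null -----
study_wilcoxon_null <- function(n_sims = 1000, seed = 1, n_samples = 23,
                                n_families = 10, alpha = 0.05) {
  groups <- rep(c("g1", "g2"), c(12, n_samples - 12))
  flags <- withr::with_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      m <- matrix(stats::rlnorm(n_samples * n_families, 1, 0.5),
                  nrow = n_samples,
                  dimnames = list(NULL, paste0("fam", seq_len(n_families))))
      ab <- bind_cols(tibble(sample_id = paste0("S", seq_len(n_samples))),
                      as_tibble(m))
      cmp <- compare_landscapes(ab, groups = groups, alpha = alpha, seed = i)
      mean(cmp$tests$significant)
    }, double(1))
  })
  list(flag_rate = mean(flags), n_sims = n_sims, alpha = alpha)
}

# --- satellite monomer-period recovery --------------------------------------
study_period_recovery <- function(n_arrays = 40, seed = 1, divergence = 0.05,
                                  monomers = c(107L, 187L, 677L, 964L, 994L)) {
  rows <- lapply(monomers, function(L) {
    n_cop <- max(12L, ceiling(4500 / L))
    hits <- vapply(seq_len(n_arrays), function(i) {
      s <- seed + L * 1000L + i
      sim <- sim_reference(
        c(chr1 = L * n_cop + 2000L),
        events = tibble(kind = "satellite_array", chrom = "chr1", start = 1000L,
                        monomer_length = L, n_copies = n_cop,
                        divergence = divergence, family_id = "s"),
        seed = s
      )
      arr <- substr(as.character(sim$genome)[["chr1"]], 1001L, 1000L + L * n_cop)
      isTRUE(estimate_period(arr) == L)
    }, logical(1))
    tibble(monomer_length = L, recovery_rate = mean(hits), n_arrays = n_arrays)
  })
  bind_rows(rows)
}

# --- implanted 43-nt palindrome detection -----------------------------------
study_palindrome <- function(seed = 1) {
  res <- withr::with_seed(seed, {
    arm <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(arm)))
    pal <- strsplit(paste0(arm, "A", rc), "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    bad <- function(b) setdiff(c("A", "C", "G", "T"), c(b, comp[[b]]))[1]
    pal[3] <- bad(pal[43 - 3 + 1])
    pal[40] <- bad(pal[43 - 40 + 1])
    monomer <- paste0("AAAAA", paste(pal, collapse = ""), "AAAAA")
    find_palindrome(monomer, min_length = 20, max_mismatch = 2)
  })
  list(length_found = res$length, mismatches = res$mismatches)
}

# --- in-silico FISH on a synthetic diploid ----------------------------------
# one satellite array shared by both haplotypes plus one haplotype-2-only
# array; expect exactly (1 shared pair, 1 hemizygous locus).
study_fish <- function(seed = 1) {
  sim <- sim_reference(
    c(chr10 = 200000, chr15 = 200000),
    events = tibble(kind = "satellite_array", chrom = "chr10", start = 50000L,
                    monomer_length = 320L, n_copies = 30L, divergence = 0.03,
                    family_id = "satH"),
    seed = seed
  )
  hap1 <- stats::setNames(as.character(sim$genome), names(sim$genome))
  arr <- substr(hap1[["chr10"]], 50001L, 50000L + 320L * 30L)
  hap2 <- hap1
  substr(hap2[["chr15"]], 100001L, 100000L + nchar(arr)) <- arr
  fam <- characterize_satellite(arr, id = "satH")
  loci1 <- call_tandem_loci(map_monomer(fam$consensus, hap1), fam$monomer_length)
  loci2 <- call_tandem_loci(map_monomer(fam$consensus, hap2), fam$monomer_length)
  res <- compare_haplotypes(loci1, loci2)
  list(
    n_shared = sum(res$status == "shared" & res$haplotype == "h1"),
    n_hemizygous = sum(res$status == "hemizygous"),
    monomer_length = fam$monomer_length
  )
}

# --- fixed-unmasked-size window invariant over randomized masks -------------
study_window_invariant <- function(n_masks = 10, seed = 1, w = 1000L) {
  ok <- vapply(seq_len(n_masks), function(i) {
    frac <- 0.1 + 0.3 * (i / n_masks)
    sim <- sim_reference(c(chr1 = 100000), masked_fraction = frac,
                         seed = seed + i)
    win <- define_windows(sim, w = w)
    masked <- logical(100000)
    for (j in seq_len(nrow(sim$mask)))
      masked[(sim$mask$start[j] + 1):sim$mask$end[j]] <- TRUE
    exact <- all(vapply(seq_len(nrow(win)), function(k)
      sum(!masked[(win$start[k] + 1):win$end[k]]) == w, logical(1)))
    dropped <- nrow(win) == sum(!masked) %/% w
    exact && dropped
  }, logical(1))
  mean(ok)
}
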