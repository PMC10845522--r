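test_that("period estimation recovers monomer lengths from diverged arrays", {
  a107 <- make_array(107, 50, divergence = 0.02, seed = 80)
  expect_equal(estimate_period(a107$array), 107L)
  a187 <- make_array(187, 40, divergence = 0.02, seed = 81)
  expect_equal(estimate_period(a187$array), 187L)

  # i.i.d. random sequence has no significant period
  rnd <- withr::with_seed(82, vitiscan:::random_dna(5000, gc = 0.5))
  expect_true(is.na(estimate_period(rnd)))

  expect_error(estimate_period("ACGTACGT"), "shorter than 30")
})

test_that("period estimation pools several fragments of one array", {
  fix <- make_array(107, 60, divergence = 0.03, seed = 83)
  pieces <- substring(fix$array, c(1, 2001, 4001), c(2000, 4000, 6420))
  expect_equal(estimate_period(pieces), 107L)
})

test_that("consensus building takes the per-column majority", {
  # identical frames reproduce the monomer exactly
  fix <- make_array(53, 10, divergence = 0, seed = 84)
  expect_equal(build_consensus(fix$array, 53), fix$monomer)

  # 2% divergence over 50 frames still yields the exact monomer
  fix2 <- make_array(107, 50, divergence = 0.02, seed = 85)
  expect_equal(build_consensus(fix2$array, 107), fix2$monomer)

  # 50/50 column ties break to the lexicographically smallest base
  expect_equal(build_consensus(c("AT", "AT", "AA", "AA"), 2), "AA")

  expect_error(build_consensus("ACGTACGT", 4), "3 full frames")
})

test_that("A/T content follows its definition and excludes N", {
  expect_equal(at_content("ATAT"), 1)
  expect_equal(at_content("GCGC"), 0)
  expect_equal(at_content("ATGC"), 0.5)
  expect_equal(at_content("ATGCNN"), 0.5)
  expect_error(at_content("NNNN"), "no A/C/G/T")
  expect_error(at_content(""), "empty")
})

test_that("consensus A/T content tracks the generator's target composition", {
  for (target in c(0.5, 0.65, 0.77)) {
    fix <- make_array(300, 30, divergence = 0.02, at_fraction = target,
                      seed = 86 + round(100 * target))
    cons <- build_consensus(fix$array, 300)
    expect_lt(abs(at_content(cons) - target), 0.03 + 3 * sqrt(target * (1 - target) / 300))
  }
})

test_that("palindrome search finds an implanted near-palindrome at its length", {
  # 43-nt palindrome: 21-bp arms with 2 mismatches + unpaired center.
  withr::with_seed(90, {
    arm <- vitiscan:::random_dna(21, gc = 0.5)
    pal <- paste0(arm, "A", vitiscan:::revcomp(arm))
    pal_chars <- strsplit(pal, "")[[1]]
  })
  # introduce 2 arm mismatches (positions 3 and 40 lose their partners)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bad <- function(b) setdiff(c("A", "C", "G", "T"), c(b, comp[[b]]))[1]
  pal_chars[3] <- bad(pal_chars[43 - 3 + 1])
  pal_chars[40] <- bad(pal_chars[43 - 40 + 1])
  pal43 <- paste(pal_chars, collapse = "")
  # flanks chosen so any extension is a third mismatch
  monomer <- paste0("AAAAA", pal43, "AAAAA")
  hit <- find_palindrome(monomer, min_length = 20, max_mismatch = 2)
  expect_equal(hit$length, 43L)
  expect_equal(hit$mismatches, 2L)
  expect_equal(hit$offset, 5L)

  # threshold behavior on a single internal mismatch
  withr::with_seed(91, arm2 <- vitiscan:::random_dna(12, gc = 0.5))
  pal24 <- paste0(arm2, vitiscan:::revcomp(arm2))
  p2 <- strsplit(pal24, "")[[1]]
  p2[2] <- bad(p2[24 - 2 + 1])
  mono2 <- paste0("CCCCC", paste(p2, collapse = ""), "CCCCC")
  expect_equal(find_palindrome(mono2, min_length = 24, max_mismatch = 1)$length, 24L)
  expect_null(find_palindrome(mono2, min_length = 24, max_mismatch = 0))

  expect_error(find_palindrome("ACGT", min_length = 20), "shorter")
})

test_that("random monomers contain no long palindromes", {
  hits <- vapply(1:100, function(s) {
    mono <- withr::with_seed(1000 + s, vitiscan:::random_dna(100, gc = 0.5))
    !is.null(find_palindrome(mono, min_length = 40, max_mismatch = 2))
  }, logical(1))
  expect_equal(sum(hits), 0L)
})

test_that("monomer mapping recovers implanted arrays and respects strand
           symmetry", {
  fix <- make_array(107, 30, divergence = 0.03, seed = 92)
  bg <- withr::with_seed(93, vitiscan:::random_dna(50000, gc = 0.35))
  chrom <- paste0(substr(bg, 1, 20000), fix$array, substr(bg, 20001, 50000))
  asm <- c(chr1 = chrom)
  hits <- map_monomer(fix$monomer, asm)
  expect_gte(nrow(hits), 28L)
  expect_lte(nrow(hits), 32L)
  expect_true(all(hits$start >= 19900 & hits$end <= 20000 + 30 * 107 + 100))

  # absent monomer: no hits
  other <- make_array(107, 1, divergence = 0, seed = 94)
  expect_equal(nrow(map_monomer(other$monomer, c(chr1 = bg))), 0L)

  # mapping the reverse-complemented assembly flips strand and mirrors position
  rc_asm <- c(chr1 = vitiscan:::revcomp(chrom))
  hits_rc <- map_monomer(fix$monomer, rc_asm)
  expect_equal(nrow(hits_rc), nrow(hits))
  expect_equal(sort(nchar(chrom) - hits_rc$end), sort(hits$start))
  expect_true(all(hits_rc$strand == "-"))
})

test_that("tandem loci chain nearby hits and honor the minimum hit count", {
  hits <- tibble(chrom = "chr1",
                 start = (0:29) * 107L, end = (1:30) * 107L,
                 strand = "+", identity = 0.95)
  loci <- call_tandem_loci(hits, 107)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$n_hits, 30L)

  two <- bind_rows(hits, dplyr::mutate(hits, start = start + 50000L,
                                       end = end + 50000L))
  expect_equal(nrow(call_tandem_loci(two, 107)), 2L)

  expect_equal(nrow(call_tandem_loci(hits[1:4, ], 107)), 0L)
  expect_equal(locus_site_counts(call_tandem_loci(two, 107))$n_sites, 2L)
})

test_that("haplotype comparison separates shared and hemizygous loci", {
  l1 <- tibble(chrom = c("chr10", "chr15"), start = c(1000L, 5000L),
               end = c(4000L, 9000L), n_hits = c(20L, 25L),
               mean_identity = 0.95, frac_forward = 1)
  # identical locus sets: nothing hemizygous
  res0 <- compare_haplotypes(l1, l1)
  expect_true(all(res0$status == "shared"))

  # drop the chr15 locus from haplotype 2: it becomes hemizygous in h1
  res1 <- compare_haplotypes(l1, l1[1, ])
  expect_equal(res1$status[res1$haplotype == "h1" & res1$chrom == "chr15"],
               "hemizygous")
  expect_equal(sum(res1$status == "shared"), 2L)

  # explicit homology table with different naming
  hom <- tibble(h1_chrom = c("chr10", "chr15"), h2_chrom = c("h2_10", "h2_15"))
  l2 <- dplyr::mutate(l1[1, ], chrom = "h2_10")
  res2 <- compare_haplotypes(l1, l2, homology = hom)
  expect_equal(sum(res2$status == "hemizygous"), 1L)
  expect_error(compare_haplotypes(l1, dplyr::mutate(l2, chrom = "weird"),
                                  homology = hom), "absent from homology")
})

test_that("end-to-end characterization reports period, composition and
           palindrome together", {
  fix <- make_array(187, 40, divergence = 0.02, at_fraction = 0.6, seed = 95)
  fam <- characterize_satellite(fix$array, id = "satX")
  expect_equal(fam$monomer_length, 187L)
  expect_equal(nchar(fam$consensus), 187L)
  expect_lt(abs(fam$at_fraction - at_content(fix$monomer)), 0.02)
  rnd <- withr::with_seed(96, vitiscan:::random_dna(3000, gc = 0.5))
  expect_error(characterize_satellite(rnd), "no significant monomer period")
})
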