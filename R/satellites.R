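#' Estimate the monomer period of tandem-repeat sequences
#'
#' For every candidate period p the shifted-identity score is the fraction of
#' positions i with `base(i) == base(i + p)`, pooled over the input
#' sequences. The reported period is the smallest p whose score is a local
#' maximum exceeding `min_score` and at least `min_above_background` above
#' the median score over all candidates; preferring the smallest significant
#' period avoids reporting dimer or higher multimer harmonics.
#'
#' @param sequences character vector (or [Biostrings::DNAStringSet]) of
#'   tandem-derived sequences; pooled length must be at least 30 nt and at
#'   least 3 times the candidate period.
#' @param min_period,max_period candidate period range (nt).
#' @param min_score minimal shifted-identity score.
#' @param min_above_background required margin over the median score.
#' @return the estimated monomer length (integer), or `NA` when no period
#'   qualifies.
#' @examples
#' arr <- strrep("ACGTGATTACAGGCCT", 20)
#' estimate_period(arr)   # 16
#' @export
estimate_period <- function(sequences, min_period = 10, max_period = 2000,
                            min_score = 0.8, min_above_background = 0.05) {
  if (!is.character(sequences)) sequences <- as.character(sequences)
  lens <- nchar(sequences)
  total <- sum(lens)
  if (total < 30) abort("input shorter than 30 nt")
  p_hi <- min(max_period, floor(total / 3))
  if (p_hi < min_period) return(NA_integer_)
  ints <- lapply(sequences, function(s) utf8ToInt(s))
  cand <- min_period:p_hi
  match_n <- numeric(length(cand))
  pos_n <- numeric(length(cand))
  for (x in ints) {
    L <- length(x)
    for (j in seq_along(cand)) {
      p <- cand[j]
      if (L <= p) next
      match_n[j] <- match_n[j] + sum(x[1:(L - p)] == x[(p + 1):L])
      pos_n[j] <- pos_n[j] + (L - p)
    }
  }
  score <- ifelse(pos_n > 0, match_n / pos_n, 0)
  bg <- median(score)
  n <- length(score)
  local_max <- score >= c(-Inf, score[-n]) & score >= c(score[-1], -Inf)
  ok <- local_max & score > min_score & score >= bg + min_above_background
  if (!any(ok)) return(NA_integer_)
  as.integer(cand[which(ok)[1]])
}

#' Build a consensus monomer from tandem sequences at a known period
#'
#' Sequences are cut into period-phased frames and the consensus takes the
#' majority base per column (ties broken by the lexicographically smallest
#' base, so the consensus is IUPAC-free). All rotations of a tandem array
#' give the same per-column agreement, so the consensus is reported in the
#' phase of the array start; compare consensus sequences up to rotation.
#'
#' @param sequences character vector of tandem-derived sequences.
#' @param period monomer length from [estimate_period()].
#' @return consensus monomer (character scalar of length `period`).
#' @export
build_consensus <- function(sequences, period) {
  if (!is.character(sequences)) sequences <- as.character(sequences)
  period <- as.integer(period)
  n_frames <- sum(nchar(sequences) %/% period)
  if (n_frames < 3) abort("need at least 3 full frames at this period")
  counts <- matrix(0L, nrow = 4, ncol = period,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (s in sequences) {
    x <- strsplit(s, "", fixed = TRUE)[[1]]
    col <- ((seq_along(x) - 1L) %% period) + 1L
    for (b in rownames(counts)) {
      hit <- x == b
      if (any(hit)) {
        t <- tabulate(col[hit], nbins = period)
        counts[b, ] <- counts[b, ] + t
      }
    }
  }
  # which.max takes the first (lexicographically smallest) base on ties
  paste(rownames(counts)[apply(counts, 2, which.max)], collapse = "")
}

#' A/T content of a sequence
#'
#' `(A + T) / (A + C + G + T)`; `N` bases are excluded from numerator and
#' denominator.
#'
#' @param sequence character scalar (or something coercible via
#'   `as.character`).
#' @return fraction in `[0, 1]`.
#' @examples
#' at_content("ATGC")  # 0.5
#' @export
at_content <- function(sequence) {
  s <- toupper(as.character(sequence)[1])
  if (!nchar(s)) abort("empty sequence")
  r <- charToRaw(s)
  at <- sum(r %in% charToRaw("AT"))
  acgt <- sum(r %in% charToRaw("ACGT"))
  if (acgt == 0) abort("sequence contains no A/C/G/T bases")
  at / acgt
}

#' Find the best reverse-complement palindrome in a monomer
#'
#' Scans the monomer circularly (the tandem context makes it a circle) for
#' the longest substring equal to its own reverse complement with at most
#' `max_mismatch` mismatching base pairs. The center base of an odd-length
#' palindrome is unpaired (a one-base hairpin loop) and does not count as a
#' mismatch. Ties are broken by fewer mismatches, then smaller offset.
#'
#' @param monomer character scalar, length at least `min_length`.
#' @param min_length minimal palindrome length (nt).
#' @param max_mismatch maximal tolerated mismatches.
#' @return tibble with one row (`offset` 0-based on the monomer, `length`,
#'   `mismatches`) or `NULL` when none qualifies.
#' @export
find_palindrome <- function(monomer, min_length = 20, max_mismatch = 2) {
  s <- toupper(as.character(monomer)[1])
  len <- nchar(s)
  if (len < min_length) abort("monomer shorter than `min_length`")
  d <- strsplit(paste0(s, s), "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pair_ok <- function(i, j) {
    !is.na(comp[d[i]]) && comp[d[i]] == d[j]
  }
  best <- NULL
  consider <- function(offset, length, mism) {
    offset <- offset %% len
    if (is.null(best) ||
        length > best$length ||
        (length == best$length && mism < best$mismatches) ||
        (length == best$length && mism == best$mismatches && offset < best$offset)) {
      best <<- list(offset = offset, length = length, mismatches = mism)
    }
  }
  max_arm <- len %/% 2
  for (c1 in seq_len(2L * len - 1L)) {
    # even lengths centered between c1 and c1+1
    mism <- 0L
    for (a in seq_len(max_arm)) {
      i <- c1 - a + 1L; j <- c1 + a
      if (i < 1L || j > 2L * len) break
      if (!pair_ok(i, j)) mism <- mism + 1L
      if (mism > max_mismatch) break
      if (2L * a >= min_length) consider(i - 1L, 2L * a, mism)
    }
    # odd lengths centered on c1 (the center base is an unpaired loop base)
    mism <- 0L
    for (a in seq_len(max_arm)) {
      i <- c1 - a; j <- c1 + a
      if (i < 1L || j > 2L * len) break
      if (!pair_ok(i, j)) mism <- mism + 1L
      if (mism > max_mismatch) break
      if (2L * a + 1L >= min_length && 2L * a + 1L <= len)
        consider(i - 1L, 2L * a + 1L, mism)
    }
  }
  if (is.null(best)) return(NULL)
  tibble(offset = as.integer(best$offset), length = as.integer(best$length),
         mismatches = as.integer(best$mismatches))
}

#' Map a satellite monomer onto an assembly
#'
#' Ungapped sliding alignment of the monomer along both strands of every
#' chromosome; local matches with identity at or above `min_identity` are
#' reported and reduced to non-overlapping hits (best identity first), in
#' deterministic coordinate order.
#'
#' @param monomer character scalar.
#' @param assembly named character vector of chromosome sequences, a
#'   [Biostrings::DNAStringSet], or a `sim_genome`.
#' @param min_identity minimal identity of a hit.
#' @return tibble `chrom`, `start`, `end` (0-based half-open), `strand`,
#'   `identity`.
#' @export
map_monomer <- function(monomer, assembly, min_identity = 0.8) {
  if (inherits(assembly, "sim_genome")) assembly <- assembly$genome
  if (!is.character(assembly))
    assembly <- stats::setNames(as.character(assembly), names(assembly))
  monomer <- toupper(as.character(monomer)[1])
  m <- nchar(monomer)
  rc <- revcomp(monomer)
  out <- list()
  for (chrom in names(assembly)) {
    s <- assembly[[chrom]]
    if (nchar(s) < m) {
      warn(paste0("monomer longer than ", chrom, "; skipped"))
      next
    }
    hits <- bind_rows(
      as_tibble(.scan_monomer(s, monomer, min_identity)) |> mutate(strand = "+"),
      as_tibble(.scan_monomer(s, rc, min_identity)) |> mutate(strand = "-")
    )
    if (!nrow(hits)) next
    # keep best-identity non-overlapping hits
    hits <- hits[order(-hits$identity, hits$pos), ]
    kept_start <- integer(0)
    keep <- logical(nrow(hits))
    for (i in seq_len(nrow(hits))) {
      p <- hits$pos[i]
      if (!length(kept_start) || all(abs(kept_start - p) >= m)) {
        keep[i] <- TRUE
        kept_start <- c(kept_start, p)
      }
    }
    h <- hits[keep, ]
    out[[chrom]] <- tibble(
      chrom = chrom, start = h$pos, end = h$pos + m,
      strand = h$strand, identity = h$identity
    )
  }
  res <- bind_rows(out)
  if (!nrow(res))
    res <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), identity = double())
  arrange(res, .data$chrom, .data$start)
}

#' Chain monomer hits into tandem loci
#'
#' Hits on one chromosome are chained while the gap between consecutive hits
#' does not exceed `max_gap`; chains with at least `min_hits` monomer matches
#' become tandem loci. The per-chromosome locus count is the in-silico
#' analogue of a FISH site count.
#'
#' @param hits tibble from [map_monomer()].
#' @param monomer_length monomer length (nt), used for the default gap.
#' @param max_gap maximal gap between consecutive hits within one locus.
#' @param min_hits minimal monomer matches per locus.
#' @return tibble `chrom`, `start`, `end`, `n_hits`, `mean_identity`,
#'   `frac_forward`.
#' @export
call_tandem_loci <- function(hits, monomer_length,
                             max_gap = 2 * monomer_length, min_hits = 5) {
  out <- list()
  for (chrom in unique(hits$chrom)) {
    h <- hits[hits$chrom == chrom, ]
    h <- h[order(h$start), ]
    gap <- c(0, h$start[-1] - h$end[-nrow(h)])
    grp <- cumsum(gap > max_gap)
    for (g in unique(grp)) {
      hg <- h[grp == g, ]
      if (nrow(hg) < min_hits) next
      out[[length(out) + 1L]] <- tibble(
        chrom = chrom, start = hg$start[1], end = hg$end[nrow(hg)],
        n_hits = nrow(hg), mean_identity = mean(hg$identity),
        frac_forward = mean(hg$strand == "+")
      )
    }
  }
  res <- bind_rows(out)
  if (!nrow(res))
    res <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_hits = integer(), mean_identity = double(),
                  frac_forward = double())
  arrange(res, .data$chrom, .data$start)
}

#' Per-chromosome tandem-site counts
#'
#' @param loci tibble from [call_tandem_loci()].
#' @return tibble `chrom`, `n_sites`.
#' @export
locus_site_counts <- function(loci) {
  count(loci, .data$chrom, name = "n_sites")
}

#' Compare satellite loci between two haplotype assemblies
#'
#' Loci are matched across haplotypes on homologous chromosomes when their
#' reciprocal overlap reaches `min_overlap`; unmatched loci are flagged
#' hemizygous (present on only one haplotype), the in-silico analogue of
#' unpaired FISH signals at pachytene.
#'
#' @param loci_h1,loci_h2 locus tibbles from [call_tandem_loci()], one per
#'   haplotype.
#' @param homology tibble with columns `h1_chrom`, `h2_chrom` mapping
#'   homologous chromosome names; `NULL` matches identical names. A locus
#'   chromosome absent from a supplied table is an error.
#' @param min_overlap minimal reciprocal overlap (fraction of each locus).
#' @return tibble `haplotype`, `chrom`, `start`, `end`, `n_hits`, `status`
#'   (`shared`/`hemizygous`); the summary counts are available with
#'   `dplyr::count(result, haplotype, status)`.
#' @export
compare_haplotypes <- function(loci_h1, loci_h2, homology = NULL,
                               min_overlap = 0.1) {
  if (is.null(homology)) {
    chroms <- union(loci_h1$chrom, loci_h2$chrom)
    homology <- tibble(h1_chrom = chroms, h2_chrom = chroms)
  }
  stopifnot(all(c("h1_chrom", "h2_chrom") %in% names(homology)))
  bad1 <- setdiff(loci_h1$chrom, homology$h1_chrom)
  bad2 <- setdiff(loci_h2$chrom, homology$h2_chrom)
  if (length(bad1) || length(bad2))
    abort(paste0("chromosome(s) absent from homology table: ",
                 paste(c(bad1, bad2), collapse = ", ")))
  h1 <- loci_h1; h2 <- loci_h2
  h1$.hom <- homology$h2_chrom[match(h1$chrom, homology$h1_chrom)]
  matched1 <- logical(nrow(h1))
  matched2 <- logical(nrow(h2))
  for (i in seq_len(nrow(h1))) {
    cand <- which(h2$chrom == h1$.hom[i] & !matched2)
    for (j in cand) {
      ov <- min(h1$end[i], h2$end[j]) - max(h1$start[i], h2$start[j])
      if (ov <= 0) next
      if (ov / (h1$end[i] - h1$start[i]) >= min_overlap &&
          ov / (h2$end[j] - h2$start[j]) >= min_overlap) {
        matched1[i] <- TRUE
        matched2[j] <- TRUE
        break
      }
    }
  }
  bind_rows(
    h1 |> select(-".hom") |> mutate(haplotype = "h1",
                                    status = ifelse(matched1, "shared", "hemizygous")),
    h2 |> mutate(haplotype = "h2",
                 status = ifelse(matched2, "shared", "hemizygous"))
  ) |>
    select("haplotype", dplyr::everything()) |>
    arrange(.data$haplotype, .data$chrom, .data$start)
}

#' Characterize a satellite family end to end
#'
#' Convenience wrapper: estimate the monomer period of the input tandem
#' sequences, build the consensus monomer, and derive its A/T content and
#' best internal palindrome.
#'
#' @param sequences tandem-derived sequences (character vector).
#' @param id family identifier.
#' @param genome_proportion optional genome proportion (%) to store.
#' @param ... passed to [estimate_period()].
#' @return object of class `satellite_family`: list with `id`, `consensus`,
#'   `monomer_length`, `at_fraction`, `genome_proportion`, `palindrome`.
#' @export
characterize_satellite <- function(sequences, id = "sat", genome_proportion = NA_real_,
                                   ...) {
  period <- estimate_period(sequences, ...)
  if (is.na(period))
    abort("no significant monomer period found; not a tandem repeat?")
  cons <- build_consensus(sequences, period)
  structure(
    list(
      id = id,
      consensus = cons,
      monomer_length = period,
      at_fraction = at_content(cons),
      genome_proportion = genome_proportion,
      palindrome = if (period >= 20) find_palindrome(cons) else NULL
    ),
    class = "satellite_family"
  )
}

#' @export
print.satellite_family <- function(x, ...) {
  cat("<satellite_family> ", x$id, ": monomer ", x$monomer_length, " nt, A/T ",
      round(100 * x$at_fraction), "%",
      if (!is.null(x$palindrome))
        paste0(", palindrome ", x$palindrome$length, " nt (",
               x$palindrome$mismatches, " mm)"),
      "\n", sep = "")
  invisible(x)
}
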