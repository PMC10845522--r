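#' Simulate a reference genome with implanted events and recorded ground truth
#'
#' Builds a multi-chromosome reference of random background sequence at a given
#' GC content, implants the requested features, and records every implanted
#' event in a truth table so downstream callers can be scored against known
#' answers. Two families of events exist:
#'
#' * **sequence features** (`satellite_array`, `dispersed_family`) are written
#'   into the reference sequence itself and are shared by all samples;
#' * **copy-number events** (`duplication`, `deletion`) belong to one
#'   `sample_id` and only affect that sample's copy-number track (depth is
#'   later simulated on reference coordinates with CN-weighted rates, so no
#'   rearranged genome or aligner is needed).
#'
#' A satellite array is built by drawing a random monomer of the requested
#' length and A/T content and concatenating `n_copies` copies, each copy
#' independently mutated by substitutions at the requested `divergence`.
#' A dispersed family draws one random master element and implants `n_copies`
#' diverged copies at random non-overlapping positions.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp), or a
#'   tibble with columns `chrom`, `length`.
#' @param events `NULL` or a tibble of requested events with columns (all but
#'   `kind` optional depending on kind): `sample_id`, `chrom`, `start`
#'   (0-based), `kind` in `duplication`, `deletion`, `satellite_array`,
#'   `dispersed_family`; `cn`, `start` and `end` for CN events; `family_id`,
#'   `monomer_length`, `n_copies`, `divergence`, `at_fraction` for satellite
#'   arrays; `family_id`, `element_length`, `n_copies` (or `proportion` of the
#'   genome), `divergence` for dispersed families.
#' @param samples character vector of sample ids that exist even without
#'   events (their CN track is a flat diploid 2).
#' @param masked_fraction fraction of each chromosome covered by the repeat
#'   mask, in `[0, 1)`. Mask intervals are placed independently of events.
#' @param mask_mean_length mean masked-interval length (bp).
#' @param mask_satellites if `TRUE`, satellite arrays and dispersed copies are
#'   added to the mask, mimicking a repeat-masked reference.
#' @param gc background GC fraction (grapevine-like 0.35 by default).
#' @param seed integer seed; output is a pure function of the arguments.
#' @return an object of class `sim_genome`: a list with `genome`
#'   ([Biostrings::DNAStringSet]), `chrom_lengths`, `mask` (tibble `chrom`,
#'   `start`, `end`, 0-based half-open), `truth` (tibble of implanted events,
#'   with the drawn monomer for satellite arrays), `families` (tibble
#'   `family_id`, `kind`, `sequence` of the drawn master sequences, usable as
#'   a labeled repeat reference) and `samples`.
#' @examples
#' sim <- sim_reference(c(chr1 = 50000), seed = 1)
#' sim$chrom_lengths
#' @export
sim_reference <- function(chrom_lengths, events = NULL, samples = NULL,
                          masked_fraction = 0, mask_mean_length = 500,
                          mask_satellites = FALSE, gc = 0.35, seed = 1) {
  cl <- as_chrom_lengths(chrom_lengths)
  if (any(cl$length <= 0)) abort("chromosome lengths must be > 0")
  if (masked_fraction < 0 || masked_fraction >= 1)
    abort("`masked_fraction` must be in [0, 1)")
  withr::local_seed(seed)

  seqs <- lapply(cl$length, random_dna, gc = gc)
  names(seqs) <- cl$chrom

  truth <- normalize_events(events, cl)
  truth <- place_dispersed(truth, cl)
  check_event_overlaps(truth)

  # implant sequence features; chromosomes are edited as raw vectors so each
  # insertion avoids re-copying the whole sequence string
  feat <- which(truth$kind %in% c("satellite_array", "dispersed_family"))
  for (chrom in unique(truth$chrom[feat])) {
    r <- charToRaw(seqs[[chrom]])
    for (i in feat[truth$chrom[feat] == chrom]) {
      ev <- truth[i, ]
      if (ev$kind == "satellite_array") {
        monomer <- random_dna(ev$monomer_length, gc = 1 - ev$at_fraction)
        n_cop <- (ev$end - ev$start) / ev$monomer_length
        copies <- vapply(seq_len(n_cop), function(j) mutate_seq(monomer, ev$divergence),
                         character(1))
        insert <- paste(copies, collapse = "")
        truth$monomer[i] <- monomer
      } else {
        insert <- mutate_seq(truth$element[i], ev$divergence)
      }
      r[(ev$start + 1L):ev$end] <- charToRaw(insert)
    }
    seqs[[chrom]] <- rawToChar(r)
  }
  seqf <- truth[truth$kind %in% c("satellite_array", "dispersed_family"), ]
  families <- tibble(family_id = character(), kind = character(), sequence = character())
  if (nrow(seqf)) {
    families <- seqf |>
      mutate(sequence = ifelse(.data$kind == "satellite_array",
                               .data$monomer, .data$element)) |>
      dplyr::distinct(.data$family_id, .data$kind, .data$sequence)
  }
  truth$element <- NULL

  mask <- sim_mask(cl, masked_fraction, mask_mean_length)
  if (mask_satellites) {
    arr <- truth[truth$kind %in% c("satellite_array", "dispersed_family"),
                 c("chrom", "start", "end")]
    mask <- merge_intervals(bind_rows(mask, arr))
  }

  structure(
    list(
      genome = Biostrings::DNAStringSet(unlist(seqs)),
      chrom_lengths = cl,
      mask = mask,
      truth = truth,
      families = families,
      samples = sort(unique(c(samples, truth$sample_id[!is.na(truth$sample_id)])))
    ),
    class = "sim_genome"
  )
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome> ", nrow(x$chrom_lengths), " chromosomes, ",
      format(sum(x$chrom_lengths$length), big.mark = ","), " bp; ",
      nrow(x$mask), " mask intervals; ", nrow(x$truth), " truth events; samples: ",
      if (length(x$samples)) paste(x$samples, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

# fill defaults and end coordinates for requested events
normalize_events <- function(events, cl) {
  template <- tibble(
    sample_id = character(), chrom = character(), start = integer(),
    end = integer(), kind = character(), cn = double(), family_id = character(),
    monomer_length = integer(), n_copies = integer(), divergence = double(),
    at_fraction = double(), element_length = integer(), proportion = double(),
    monomer = character(), element = character()
  )
  if (is.null(events) || nrow(as_tibble(events)) == 0) {
    template$proportion <- NULL
    template$element_length <- NULL
    return(template)
  }
  ev <- as_tibble(events)
  for (col in setdiff(names(template), names(ev))) ev[[col]] <- template[[col]][NA_integer_][seq_len(nrow(ev))]
  bad <- setdiff(names(ev), names(template))
  if (length(bad)) abort(paste0("unknown event columns: ", paste(bad, collapse = ", ")))
  if (any(!ev$kind %in% c("duplication", "deletion", "satellite_array", "dispersed_family")))
    abort("event `kind` must be duplication, deletion, satellite_array or dispersed_family")

  cnev <- ev$kind %in% c("duplication", "deletion")
  if (any(cnev & is.na(ev$cn))) abort("CN events need a `cn` value")
  if (any(ev$kind == "duplication" & ev$cn <= 2))
    abort("duplications must have cn > 2")
  if (any(ev$kind == "deletion" & ev$cn >= 2))
    abort("deletions must have cn < 2")
  ev$cn[!cnev] <- 2

  sat <- ev$kind == "satellite_array"
  if (any(sat & (is.na(ev$monomer_length) | is.na(ev$n_copies))))
    abort("satellite arrays need `monomer_length` and `n_copies`")
  if (any(sat & ev$monomer_length < 10))
    abort("satellite `monomer_length` must be >= 10")
  ev$divergence[is.na(ev$divergence)] <- 0
  ev$at_fraction[is.na(ev$at_fraction)] <- 0.65
  ev$end[sat] <- ev$start[sat] + ev$monomer_length[sat] * ev$n_copies[sat]
  if (any(cnev & (is.na(ev$start) | is.na(ev$end))))
    abort("CN events need `start` and `end`")

  placed <- !ev$kind %in% "dispersed_family"
  ev_p <- ev[placed, ]
  len <- stats::setNames(cl$length, cl$chrom)
  if (any(!ev_p$chrom %in% cl$chrom)) abort("event chromosome not in reference")
  if (any(ev_p$start < 0 | ev_p$end > len[ev_p$chrom]))
    abort("event exceeds chromosome bounds")
  ev
}

# expand dispersed_family requests into per-copy rows. Placement samples
# non-overlapping candidate slots (element length + 1 kb spacer, genome-wide
# grid) without replacement, skipping slots that touch explicitly placed
# events; which slots a family receives is random under the seed. The spacer
# keeps copies of different families from being near-adjacent, which would
# let overlapping reads bridge otherwise unrelated repeat clusters.
place_dispersed <- function(truth, cl) {
  disp <- which(truth$kind == "dispersed_family")
  if (!length(disp)) {
    truth$proportion <- NULL
    truth$element_length <- NULL
    return(truth)
  }
  genome_len <- sum(cl$length)
  fixed <- truth[-disp, c("chrom", "start", "end")]
  fixed <- fixed[!is.na(fixed$end), ]
  pitch <- max(truth$element_length[disp], na.rm = TRUE) + 1000L
  slots <- list()
  for (i in seq_len(nrow(cl))) {
    n_slot <- cl$length[i] %/% pitch
    if (n_slot == 0L) next
    s <- (seq_len(n_slot) - 1L) * pitch
    e <- s + pitch
    fx <- fixed[fixed$chrom == cl$chrom[i], ]
    free <- rep(TRUE, n_slot)
    for (j in seq_len(nrow(fx)))
      free <- free & !(fx$start[j] < e & s < fx$end[j])
    if (any(free))
      slots[[length(slots) + 1L]] <- tibble(chrom = cl$chrom[i], start = s[free])
  }
  slots <- bind_rows(slots)
  out <- list()
  for (i in disp) {
    ev <- truth[i, ]
    el_len <- ev$element_length
    if (is.na(el_len)) abort("dispersed families need `element_length`")
    n_cop <- ev$n_copies
    if (is.na(n_cop)) {
      if (is.na(ev$proportion)) abort("dispersed families need `n_copies` or `proportion`")
      n_cop <- max(1L, round(ev$proportion * genome_len / el_len))
    }
    if (n_cop > nrow(slots))
      abort("could not place dispersed copies without overlap; lower the requested proportion")
    pick <- sample.int(nrow(slots), n_cop)
    master <- random_dna(el_len, gc = 1 - ev$at_fraction)
    rows <- ev[rep(1L, n_cop), ]
    rows$chrom <- slots$chrom[pick]
    rows$start <- slots$start[pick]
    rows$end <- rows$start + el_len
    rows$n_copies <- n_cop
    rows$element <- master
    slots <- slots[-pick, ]
    out[[length(out) + 1L]] <- rows
  }
  res <- bind_rows(truth[-disp, ], bind_rows(out))
  res$proportion <- NULL
  res$element_length <- NULL
  res
}

# sequence features must not overlap each other; CN events of one sample must
# not overlap each other (the same locus may vary in several samples)
check_event_overlaps <- function(truth) {
  overlap_within <- function(df, what) {
    df <- df[order(df$chrom, df$start), ]
    by_chrom <- split(df, df$chrom)
    for (d in by_chrom) {
      if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
        abort(paste0("overlapping requested events (", what, ") on ", d$chrom[1]))
    }
  }
  seqf <- truth[truth$kind %in% c("satellite_array", "dispersed_family"), ]
  if (nrow(seqf)) overlap_within(seqf, "sequence features")
  cnev <- truth[truth$kind %in% c("duplication", "deletion"), ]
  if (nrow(cnev)) {
    for (s in unique(cnev$sample_id)) {
      overlap_within(cnev[cnev$sample_id %in% s, ], paste0("sample ", s))
    }
  }
  invisible(truth)
}

# random mask intervals totalling ~fraction of each chromosome
sim_mask <- function(cl, fraction, mean_length) {
  if (fraction <= 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  out <- list()
  for (i in seq_len(nrow(cl))) {
    L <- cl$length[i]
    target <- fraction * L
    got <- 0
    iv <- list()
    attempts <- 0
    while (got < target && attempts < 10000) {
      attempts <- attempts + 1
      w <- max(50L, min(as.integer(stats::rexp(1, 1 / mean_length)), L))
      s <- sample.int(max(1L, L - w + 1L), 1) - 1L
      e <- min(s + w, L)
      clash <- FALSE
      for (v in iv) if (v[1] < e && s < v[2]) { clash <- TRUE; break }
      if (clash) next
      iv[[length(iv) + 1L]] <- c(s, e)
      got <- got + (e - s)
    }
    if (length(iv)) {
      m <- do.call(rbind, iv)
      out[[i]] <- tibble(chrom = cl$chrom[i], start = as.integer(m[, 1]), end = as.integer(m[, 2]))
    }
  }
  merge_intervals(bind_rows(out))
}

# sort and merge possibly-overlapping intervals
merge_intervals <- function(x) {
  if (!nrow(x)) return(tibble(chrom = character(), start = integer(), end = integer()))
  gr <- GenomicRanges::reduce(to_granges(x))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  ) |> arrange(.data$chrom, .data$start)
}

#' True copy-number track for one simulated sample
#'
#' The baseline copy number is the diploid 2 everywhere; intervals carrying a
#' duplication or deletion recorded for `sample_id` are overridden with their
#' true CN.
#'
#' @param sim a [sim_reference()] object.
#' @param sample_id one of `sim$samples`.
#' @return tibble of runs `chrom`, `start`, `end`, `cn` covering the genome
#'   (0-based half-open).
#' @export
derive_sample <- function(sim, sample_id) {
  stopifnot(inherits(sim, "sim_genome"))
  if (!sample_id %in% sim$samples)
    abort(paste0("unknown sample_id: ", sample_id))
  ev <- sim$truth[sim$truth$sample_id %in% sample_id &
                    sim$truth$kind %in% c("duplication", "deletion"), ]
  out <- list()
  for (i in seq_len(nrow(sim$chrom_lengths))) {
    chrom <- sim$chrom_lengths$chrom[i]
    L <- sim$chrom_lengths$length[i]
    e <- ev[ev$chrom == chrom, ]
    e <- e[order(e$start), ]
    pos <- 0L
    runs <- list()
    for (j in seq_len(nrow(e))) {
      if (e$start[j] > pos)
        runs[[length(runs) + 1L]] <- tibble(chrom = chrom, start = pos, end = e$start[j], cn = 2)
      runs[[length(runs) + 1L]] <- tibble(chrom = chrom, start = e$start[j], end = e$end[j], cn = e$cn[j])
      pos <- e$end[j]
    }
    if (pos < L)
      runs[[length(runs) + 1L]] <- tibble(chrom = chrom, start = pos, end = L, cn = 2)
    out[[i]] <- bind_rows(runs)
  }
  bind_rows(out)
}

#' Simulate per-position read-start counts from a copy-number track
#'
#' Emulates the depth signal of mapped short reads without an aligner: the
#' number of reads starting at position p is Poisson with mean
#' `coverage / read_length * CN(p) / 2`, so a CN=4 region receives twice the
#' diploid start rate and the expected total read count is
#' `coverage * genome_length / read_length`.
#'
#' @param cn_track run-length CN track from [derive_sample()].
#' @param coverage target fold coverage of the diploid background; must be > 0.
#' @param read_length read length (nt).
#' @param seed integer seed.
#' @return tibble `chrom`, `pos` (0-based), `n` (reads starting there; only
#'   positions with n > 0 are listed).
#' @export
sim_read_starts <- function(cn_track, coverage, read_length = 100, seed = 1) {
  if (coverage <= 0) abort("`coverage` must be > 0")
  if (read_length <= 0) abort("`read_length` must be > 0")
  withr::local_seed(seed)
  out <- list()
  for (i in seq_len(nrow(cn_track))) {
    s <- cn_track$start[i]; e <- cn_track$end[i]
    rate <- coverage / read_length * cn_track$cn[i] / 2
    counts <- rpois(e - s, rate)
    hit <- which(counts > 0L)
    if (length(hit)) {
      out[[length(out) + 1L]] <- tibble(
        chrom = cn_track$chrom[i],
        pos = s + hit - 1L,
        n = counts[hit]
      )
    }
  }
  res <- bind_rows(out)
  if (!nrow(res)) res <- tibble(chrom = character(), pos = integer(), n = integer())
  arrange(res, .data$chrom, .data$pos)
}

#' Simulate short reads from a simulated genome
#'
#' Reads are drawn uniformly from the (CN-weighted) sample genome, so tandem
#' arrays and dispersed repeats are represented in proportion to their genomic
#' fraction. Half of the reads are reverse-complemented. Sequencing error is a
#' per-base substitution at `error_rate`. Base qualities are flat Q30 except
#' that a configurable fraction of reads carries a short Q10 3' tail, so that
#' quality-trimming rules can be exercised.
#'
#' @param sim a [sim_reference()] object.
#' @param n_reads number of reads; alternatively give `coverage`.
#' @param coverage fold coverage used to compute `n_reads` when that is `NULL`.
#' @param sample_id if given, start positions are weighted by that sample's CN
#'   track; otherwise sampling is uniform on the reference.
#' @param read_length read length (nt); must not exceed the shortest chromosome.
#' @param error_rate substitution rate per base, in `[0, 0.2]`.
#' @param low_q_tail_frac fraction of reads receiving a low-quality (Q10) tail.
#' @param max_tail maximal tail length (bases).
#' @param seed integer seed.
#' @return tibble `id`, `sequence`, `quality`, `chrom`, `pos`, `strand`
#'   (provenance columns give the true 0-based origin on the reference).
#' @export
sim_reads <- function(sim, n_reads = NULL, coverage = NULL, sample_id = NULL,
                      read_length = 100, error_rate = 0,
                      low_q_tail_frac = 0, max_tail = 10, seed = 1) {
  stopifnot(inherits(sim, "sim_genome"))
  if (!nrow(sim$chrom_lengths) || sum(sim$chrom_lengths$length) == 0)
    abort("empty genome")
  if (error_rate < 0 || error_rate > 0.2) abort("`error_rate` must be in [0, 0.2]")
  if (read_length > min(sim$chrom_lengths$length))
    abort("`read_length` exceeds the shortest chromosome")
  if (is.null(n_reads)) {
    if (is.null(coverage)) abort("give `n_reads` or `coverage`")
    n_reads <- round(coverage * sum(sim$chrom_lengths$length) / read_length)
  }
  withr::local_seed(seed)

  cl <- sim$chrom_lengths
  eff_len <- pmax(cl$length - read_length + 1L, 1L)
  if (!is.null(sample_id)) {
    track <- derive_sample(sim, sample_id)
    track <- track[track$end - track$start > 0, ]
    w <- (track$end - track$start) * track$cn / 2
    run_idx <- sample.int(nrow(track), n_reads, replace = TRUE, prob = w)
    span <- track$end - track$start
    pos <- track$start[run_idx] +
      floor(runif(n_reads) * span[run_idx])
    chrom <- track$chrom[run_idx]
    Lmax <- cl$length[match(chrom, cl$chrom)]
    pos <- pmin(as.integer(pos), Lmax - read_length)
    pos <- pmax(pos, 0L)
  } else {
    ci <- sample.int(nrow(cl), n_reads, replace = TRUE, prob = eff_len)
    pos <- floor(runif(n_reads) * eff_len[ci])
    chrom <- cl$chrom[ci]
    pos <- as.integer(pos)
  }

  seqs_chr <- stats::setNames(as.character(sim$genome), names(sim$genome))
  reads <- substring(seqs_chr[chrom], pos + 1L, pos + read_length)

  # substitution errors on the concatenated read pool
  if (error_rate > 0) {
    raw <- charToRaw(paste(reads, collapse = ""))
    hit <- which(runif(length(raw)) < error_rate)
    if (length(hit)) {
      bases <- charToRaw("ACGT")
      repl <- bases[sample.int(4L, length(hit), replace = TRUE)]
      same <- repl == raw[hit]
      while (any(same)) {
        repl[same] <- bases[sample.int(4L, sum(same), replace = TRUE)]
        same <- repl == raw[hit]
      }
      raw[hit] <- repl
      all_reads <- rawToChar(raw)
      reads <- substring(all_reads, (seq_len(n_reads) - 1L) * read_length + 1L,
                         seq_len(n_reads) * read_length)
    }
  }

  strand <- ifelse(runif(n_reads) < 0.5, "+", "-")
  flip <- strand == "-"
  if (any(flip)) reads[flip] <- revcomp(reads[flip])

  qual <- rep(strrep("I", read_length), n_reads)
  if (low_q_tail_frac > 0) {
    low <- which(runif(n_reads) < low_q_tail_frac)
    if (length(low)) {
      t_len <- sample.int(max_tail, length(low), replace = TRUE)
      qual[low] <- paste0(strrep("I", read_length - t_len), strrep("+", t_len))
    }
  }

  tibble(
    id = paste0("read", seq_len(n_reads)),
    sequence = reads,
    quality = qual,
    chrom = chrom,
    pos = pos,
    strand = strand
  )
}
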