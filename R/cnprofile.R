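#' Define non-overlapping windows of fixed unmasked size
#'
#' Scans each chromosome left to right and closes a window whenever exactly
#' `w` unmasked bases have been accumulated, so every window contains the same
#' amount of informative sequence while its genomic span grows across masked
#' blocks (the "KbUS" windows of WSSD-style read-depth analysis). The terminal
#' partial window of a chromosome is dropped; a fully masked chromosome yields
#' no windows.
#'
#' @param genome a `sim_genome` object, or a [Biostrings::DNAStringSet].
#' @param mask tibble `chrom`, `start`, `end` (0-based half-open) of masked
#'   intervals; taken from the `sim_genome` if not given.
#' @param w unmasked bases per window (>= 100); default 1000 (1 kb).
#' @return tibble `chrom`, `start`, `end`, `unmasked`, `gc` (GC fraction of
#'   the window's unmasked bases), with the mask and chromosome lengths kept
#'   as attributes for downstream depth computation.
#' @examples
#' sim <- sim_reference(c(chr1 = 5000), seed = 1)
#' define_windows(sim, w = 1000)
#' @export
define_windows <- function(genome, mask = NULL, w = 1000) {
  if (w < 100) abort("`w` must be >= 100")
  if (inherits(genome, "sim_genome")) {
    mask <- mask %||% genome$mask
    genome <- genome$genome
  }
  mask <- mask %||% tibble(chrom = character(), start = integer(), end = integer())
  out <- list()
  for (chrom in names(genome)) {
    L <- length(genome[[chrom]])
    masked <- logical(L)
    m <- mask[mask$chrom == chrom, ]
    for (i in seq_len(nrow(m))) {
      if (m$start[i] < 0 || m$end[i] > L) abort("mask interval outside chromosome bounds")
      masked[(m$start[i] + 1L):m$end[i]] <- TRUE
    }
    idx <- which(!masked)                    # 1-based unmasked positions
    n_win <- length(idx) %/% w
    if (n_win == 0L) next
    first <- idx[(seq_len(n_win) - 1L) * w + 1L]
    last <- idx[seq_len(n_win) * w]
    is_gc <- as.integer(charToRaw(as.character(genome[[chrom]])) %in% charToRaw("CGcg"))
    cum_gc <- cumsum(is_gc[idx])
    gc <- (cum_gc[seq_len(n_win) * w] -
             c(0, cum_gc[(seq_len(n_win) - 1L) * w])[seq_len(n_win)]) / w
    out[[chrom]] <- tibble(
      chrom = chrom,
      start = first - 1L,
      end = last,
      unmasked = as.integer(w),
      gc = gc
    )
  }
  res <- bind_rows(out)
  if (!nrow(res))
    res <- tibble(chrom = character(), start = integer(), end = integer(),
                  unmasked = integer(), gc = double())
  attr(res, "mask") <- mask
  attr(res, "chrom_lengths") <- tibble(
    chrom = names(genome),
    length = as.integer(Biostrings::width(genome))
  )
  attr(res, "w") <- w
  res
}

#' Per-window raw read depth
#'
#' A read contributes to the left-most window whose unmasked bases its span
#' `[pos, pos + read_length)` overlaps, so no read is counted twice. Window
#' depth is reported as mean per-unmasked-base coverage:
#' `reads * read_length / w`.
#'
#' @param windows window tibble from [define_windows()].
#' @param read_starts tibble `chrom`, `pos`, `n` from [sim_read_starts()] (or
#'   any per-position start counts on the same coordinates).
#' @param read_length read length used to form the spans.
#' @return `windows` with an added `depth` column.
#' @export
window_depth <- function(windows, read_starts, read_length = 100) {
  mask <- attr(windows, "mask")
  cl <- attr(windows, "chrom_lengths")
  if (is.null(cl)) abort("`windows` must come from define_windows()")
  w <- attr(windows, "w")
  depth <- numeric(nrow(windows))
  win_index <- seq_len(nrow(windows))
  for (chrom in unique(windows$chrom)) {
    L <- cl$length[cl$chrom == chrom]
    rs <- read_starts[read_starts$chrom == chrom, ]
    if (!nrow(rs)) next
    if (any(rs$pos < 0 | rs$pos >= L))
      abort(paste0("read start beyond chromosome bounds on ", chrom,
                   ": coordinate system mismatch"))
    wn <- windows[windows$chrom == chrom, ]
    wi <- win_index[windows$chrom == chrom]
    masked <- logical(L)
    m <- mask[mask$chrom == chrom, ]
    for (i in seq_len(nrow(m))) masked[(m$start[i] + 1L):m$end[i]] <- TRUE
    idx <- which(!masked)
    # window id of each unmasked genomic position (NA in the dropped remainder)
    win_of <- rep(NA_integer_, L)
    n_win <- nrow(wn)
    win_of[idx[seq_len(n_win * w)]] <- rep(seq_len(n_win), each = w)
    # next unmasked, windowed position at or after p (1-based)
    nxt <- rep(Inf, L)
    pos_w <- idx[seq_len(n_win * w)]
    nxt[pos_w] <- pos_w
    nxt <- rev(cummin(rev(nxt)))
    p1 <- rs$pos + 1L
    target <- nxt[p1]
    inside <- is.finite(target) & target <= rs$pos + read_length
    if (any(inside)) {
      tab <- tapply(rs$n[inside], win_of[as.integer(target[inside])], sum)
      depth[wi[as.integer(names(tab))]] <-
        depth[wi[as.integer(names(tab))]] + as.numeric(tab)
    }
  }
  windows$depth <- depth * read_length / w
  windows
}

#' GC-bias correction of window depths
#'
#' Windows are binned by GC fraction into `n_bins` equal-width bins; each
#' window's depth is scaled by (global median depth / median depth of its GC
#' bin). Bins holding fewer than `min_bin` windows inherit the factor of the
#' nearest populated bin. With `enabled = FALSE` the depths pass through
#' unchanged (the default profile of the package's simulations carries no GC
#' bias).
#'
#' @param profile window tibble with a `depth` column.
#' @param n_bins number of GC bins.
#' @param min_bin minimal windows per bin for a bin-specific factor.
#' @param enabled set `FALSE` to disable correction.
#' @return `profile` with an added `corrected_depth` column.
#' @export
gc_correct <- function(profile, n_bins = 20, min_bin = 10, enabled = TRUE) {
  if (!enabled) {
    profile$corrected_depth <- profile$depth
    return(profile)
  }
  if (nrow(profile) < 200) abort("need >= 200 windows for stable GC bins")
  if (all(profile$depth == 0)) abort("all window depths are zero")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(profile$gc, breaks, rightmost.closed = TRUE), 1L), n_bins)
  global_med <- median(profile$depth)
  bin_med <- tapply(profile$depth, factor(bin, levels = seq_len(n_bins)), median)
  bin_n <- tapply(rep(1L, length(bin)), factor(bin, levels = seq_len(n_bins)), sum)
  bin_n[is.na(bin_n)] <- 0L
  ok <- which(bin_n >= min_bin & !is.na(bin_med) & bin_med > 0)
  if (!length(ok)) abort("no GC bin is sufficiently populated")
  factor_of <- rep(NA_real_, n_bins)
  factor_of[ok] <- global_med / bin_med[ok]
  for (b in seq_len(n_bins)) {
    if (is.na(factor_of[b])) factor_of[b] <- factor_of[ok[which.min(abs(ok - b))]]
  }
  profile$corrected_depth <- profile$depth * factor_of[bin]
  profile
}

#' Calibrate window depths to absolute copy number
#'
#' Finds the diploid control set by iterative trimming: repeatedly compute
#' mean and sd over retained windows and drop windows outside mean +/- 3 sd
#' until the set is stable. The final mean is the depth of copy number 2, and
#' every window's absolute CN is `2 * depth / control_mean`. This reproduces
#' the control-region logic of window-based CN callers in a simple, testable
#' form.
#'
#' @param profile window tibble with a `depth` (and optionally
#'   `corrected_depth`) column; at least 50 windows.
#' @param sample_id optional sample label stored on the profile.
#' @param n_sd trimming width in standard deviations.
#' @param max_iter iteration cap.
#' @return a `cn_profile`: the input tibble with `cn` added, and attributes
#'   `control_mean`, `control_sd`, `sample_id`.
#' @examples
#' sim <- sim_reference(c(chr1 = 100000), samples = "S1", seed = 1)
#' win <- define_windows(sim)
#' rs <- sim_read_starts(derive_sample(sim, "S1"), coverage = 30, seed = 1)
#' prof <- calibrate_cn(window_depth(win, rs))
#' attr(prof, "control_mean")
#' @export
calibrate_cn <- function(profile, sample_id = NULL, n_sd = 3, max_iter = 50) {
  if (nrow(profile) < 50) abort("need >= 50 windows to calibrate")
  if (!"depth" %in% names(profile) && !"corrected_depth" %in% names(profile))
    abort("`profile` must carry a depth column")
  depth <- if ("corrected_depth" %in% names(profile)) profile$corrected_depth else profile$depth
  keep <- rep(TRUE, length(depth))
  for (i in seq_len(max_iter)) {
    mu <- mean(depth[keep]); sdev <- sd(depth[keep])
    if (is.na(sdev) || sdev == 0) break
    new_keep <- depth >= mu - n_sd * sdev & depth <= mu + n_sd * sdev
    if (identical(new_keep, keep)) break
    keep <- new_keep
    if (!any(keep)) break
  }
  if (sum(keep) < 0.1 * length(depth))
    abort("control trimming removed > 90% of windows: pathological depth profile")
  mu <- mean(depth[keep]); sdev <- sd(depth[keep])
  if (mu <= 0) abort("control mean is not positive")
  out <- profile
  out$cn <- 2 * depth / mu
  attr(out, "control_mean") <- mu
  attr(out, "control_sd") <- sdev
  attr(out, "sample_id") <- sample_id
  attr(out, "mask") <- attr(profile, "mask")
  attr(out, "chrom_lengths") <- attr(profile, "chrom_lengths")
  attr(out, "w") <- attr(profile, "w")
  class(out) <- c("cn_profile", class(out))
  out
}

#' @export
print.cn_profile <- function(x, ...) {
  cat("<cn_profile>", if (!is.null(attr(x, "sample_id"))) attr(x, "sample_id"),
      ":", nrow(x), "windows, control depth",
      signif(attr(x, "control_mean"), 4), "+/-", signif(attr(x, "control_sd"), 3), "\n")
  NextMethod()
}
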