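#' Low-complexity region detection (two-pass)
#'
#' Detects low-compositional-complexity subsequences with the classic
#' two-pass sliding-window procedure.  Pass one slides a window of
#' `window` residues and flags windows whose compositional entropy (bits)
#' is at or below `locut`; maximal runs of windows with entropy at or
#' below `hicut` that contain at least one flagged window become candidate
#' regions.  Pass two refines each merged candidate to the subsequence
#' minimizing the probability of its composition (the multinomial
#' count-of-compositions measure, computed in log space).  Defaults follow
#' the standard tool settings: window 12, locut 2.2, hicut 2.5.
#'
#' Unknown residues (`'X'`) split the sequence into independently scanned
#' fragments.  Sequences (or fragments) shorter than the window yield no
#' segments.
#'
#' @param sequence one-letter sequence string.
#' @param window sliding window size (residues).
#' @param locut low-information entropy trigger (bits).
#' @param hicut extension entropy threshold (bits).
#' @return List with `segments` (data frame: start, end, 1-based inclusive)
#'   and `lcr` (percent of residues inside segments).
#' @export
seg_lcr <- function(sequence, window = 12L, locut = 2.2, hicut = 2.5) {
  chars <- strsplit(sequence, "")[[1L]]
  L <- length(chars)
  if (L == 0L) stop("empty sequence")
  known <- chars %in% AA_ALPHABET
  # fragments of known residues
  runs <- rle(known)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segs <- list()
  for (f in which(runs$values)) {
    fr <- seg_fragment(chars[starts[f]:ends[f]], window, locut, hicut)
    if (nrow(fr)) {
      fr$start <- fr$start + starts[f] - 1L
      fr$end <- fr$end + starts[f] - 1L
      segs[[length(segs) + 1L]] <- fr
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs)
              else data.frame(start = integer(0), end = integer(0))
  covered <- logical(L)
  for (r in seq_len(nrow(segments)))
    covered[segments$start[r]:segments$end[r]] <- TRUE
  list(segments = segments, lcr = 100 * sum(covered) / L)
}

window_entropy <- function(idx, window) {
  # entropy (bits) of each length-`window` window of an integer-coded
  # sequence, via incremental count updates
  L <- length(idx)
  n_win <- L - window + 1L
  ent <- numeric(n_win)
  cnt <- tabulate(idx[seq_len(window)], nbins = 20L)
  hfun <- function(cnt) {
    p <- cnt[cnt > 0] / sum(cnt)
    -sum(p * log2(p))
  }
  ent[1L] <- hfun(cnt)
  if (n_win > 1L) for (t in 2L:n_win) {
    cnt[idx[t - 1L]] <- cnt[idx[t - 1L]] - 1L
    cnt[idx[t + window - 1L]] <- cnt[idx[t + window - 1L]] + 1L
    ent[t] <- hfun(cnt)
  }
  ent
}

# log probability-of-composition of a count vector over the 20-letter
# alphabet: multinomial permutations times the multiplicity of the
# composition class, over 20^Ls equiprobable sequences
log_p0 <- function(cnt) {
  Ls <- sum(cnt)
  r <- tabulate(cnt + 1L, nbins = max(cnt) + 1L)  # r[k+1] = #types with count k
  r[1L] <- 20L - sum(r[-1L])
  lgamma(Ls + 1) - sum(lgamma(cnt + 1)) +
    lgamma(21) - sum(lgamma(r + 1)) - Ls * log(20)
}

seg_fragment <- function(chars, window, locut, hicut) {
  none <- data.frame(start = integer(0), end = integer(0))
  L <- length(chars)
  if (L < window) return(none)
  idx <- match(chars, AA_ALPHABET)
  ent <- window_entropy(idx, window)
  trigger <- ent <= locut
  if (!any(trigger)) return(none)
  extend <- ent <= hicut
  # maximal runs of extendable windows containing a trigger window
  runs <- rle(extend)
  rend <- cumsum(runs$lengths)
  rstart <- rend - runs$lengths + 1L
  cand <- list()
  for (r in which(runs$values)) {
    win_rng <- rstart[r]:rend[r]
    if (!any(trigger[win_rng])) next
    cand[[length(cand) + 1L]] <- c(rstart[r], rend[r] + window - 1L)
  }
  if (!length(cand)) return(none)
  # merge overlapping candidate spans
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 1L]), , drop = FALSE]
  merged <- cand[1L, , drop = FALSE]
  for (r in seq_len(nrow(cand))[-1L]) {
    if (cand[r, 1L] <= merged[nrow(merged), 2L] + 1L)
      merged[nrow(merged), 2L] <- max(merged[nrow(merged), 2L], cand[r, 2L])
    else merged <- rbind(merged, cand[r, , drop = FALSE])
  }
  # pass two: minimum-probability subsequence within each candidate
  out <- none
  for (r in seq_len(nrow(merged))) {
    a0 <- merged[r, 1L]; b0 <- merged[r, 2L]
    best <- c(NA_integer_, NA_integer_); best_lp <- Inf
    for (a in a0:b0) {
      cnt <- integer(20L)
      for (b in a:b0) {
        cnt[idx[b]] <- cnt[idx[b]] + 1L
        lp <- log_p0(cnt)
        if (lp < best_lp - 1e-12) {
          best_lp <- lp
          best <- c(a, b)
        }
      }
    }
    out <- rbind(out, data.frame(start = best[1L], end = best[2L]))
  }
  out
}
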