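# Independent reimplementation of the two-pass low-complexity scan, coded
# deliberately differently from the package version (explicit loops,
# table()-based entropies, factorial arithmetic) to serve as its oracle.

oracle_window_entropy <- function(chars, w) {
  n_win <- length(chars) - w + 1L
  sapply(seq_len(n_win), function(t) {
    tab <- table(chars[t:(t + w - 1L)])
    p <- as.numeric(tab) / w
    -sum(p * log2(p))
  })
}

oracle_log_p0 <- function(chars) {
  n <- length(chars)
  counts <- sapply(AA_ALPHABET, function(a) sum(chars == a))
  rvec <- sapply(0:max(counts), function(k) sum(counts == k))
  log(factorial(n)) - sum(log(factorial(counts))) +
    log(factorial(20)) - sum(log(factorial(rvec))) - n * log(20)
}

oracle_seg <- function(sequence, w = 12L, locut = 2.2, hicut = 2.5) {
  chars <- strsplit(sequence, "")[[1L]]
  L <- length(chars)
  segments <- NULL
  # fragments between unknown residues
  frag_start <- 1L
  bounds <- c(which(!chars %in% AA_ALPHABET), L + 1L)
  pos <- 1L
  for (b in bounds) {
    if (b - pos >= w) {
      fr <- chars[pos:(b - 1L)]
      ent <- oracle_window_entropy(fr, w)
      ext <- ent <= hicut
      trig <- ent <= locut
      # explicit scan for candidate runs
      t <- 1L
      cand <- NULL
      while (t <= length(ent)) {
        if (!ext[t]) { t <- t + 1L; next }
        t2 <- t
        while (t2 < length(ent) && ext[t2 + 1L]) t2 <- t2 + 1L
        if (any(trig[t:t2]))
          cand <- rbind(cand, c(t, t2 + w - 1L))
        t <- t2 + 1L
      }
      if (!is.null(cand)) {
        # merge overlapping
        cand <- cand[order(cand[, 1]), , drop = FALSE]
        merged <- cand[1, , drop = FALSE]
        if (nrow(cand) > 1) for (r in 2:nrow(cand)) {
          if (cand[r, 1] <= merged[nrow(merged), 2] + 1L)
            merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], cand[r, 2])
          else merged <- rbind(merged, cand[r, , drop = FALSE])
        }
        for (r in seq_len(nrow(merged))) {
          a0 <- merged[r, 1]; b0 <- merged[r, 2]
          best <- NULL; best_lp <- Inf
          for (a in a0:b0) for (bb in a:b0) {
            lp <- oracle_log_p0(fr[a:bb])
            if (lp < best_lp - 1e-9) { best_lp <- lp; best <- c(a, bb) }
          }
          segments <- rbind(segments,
                            c(best[1] + pos - 1L, best[2] + pos - 1L))
        }
      }
    }
    pos <- b + 1L
  }
  covered <- logical(L)
  if (!is.null(segments))
    for (r in seq_len(nrow(segments)))
      covered[segments[r, 1]:segments[r, 2]] <- TRUE
  list(segments = segments, lcr = 100 * sum(covered) / L)
}
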