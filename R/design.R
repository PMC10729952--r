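#' Sample designed sequences from logits
#'
#' Turns per-residue logits into sequences.  `"argmax"` mode returns the
#' single deterministic maximum-probability sequence, ties broken by the
#' lowest index in the fixed alphabet `ACDEFGHIKLMNPQRSTVWY`;
#' `"temperature"` mode draws `n` independent sequences from
#' `softmax(logits / T)`.  Masked positions (`NA` logit rows) emit `'X'`.
#'
#' @param logits L x 20 logit matrix (e.g. from [cgnn_forward()]).
#' @param mode `"argmax"` or `"temperature"`.
#' @param temperature sampling temperature (> 0).
#' @param n number of samples (temperature mode).
#' @param seed integer sampling seed.
#' @param id structure identifier for the returned record.
#' @return A [design_record].
#' @export
sample_sequences <- function(logits, mode = c("argmax", "temperature"),
                             temperature = 1, n = 1L, seed = 1L,
                             id = "design") {
  mode <- match.arg(mode)
  if (temperature <= 0) stop("temperature must be > 0")
  if (n < 1) stop("n must be >= 1")
  if (any(!is.finite(logits) & !is.na(logits)))
    stop("logits must be finite or NA (masked)")
  L <- nrow(logits)
  masked <- apply(logits, 1, function(r) any(is.na(r)))
  probs <- matrix(NA_real_, L, 20)
  for (i in which(!masked)) {
    z <- logits[i, ] - max(logits[i, ])
    probs[i, ] <- exp(z) / sum(exp(z))
  }
  if (mode == "argmax") {
    seqs <- rep("X", L)
    for (i in which(!masked)) seqs[i] <- AA_ALPHABET[which.max(logits[i, ])]
    return(design_record(id, probs, paste(seqs, collapse = ""),
                         temperature = 0, seed = NA_integer_))
  }
  set.seed(seed)
  out <- character(n)
  for (s in seq_len(n)) {
    seqs <- rep("X", L)
    for (i in which(!masked)) {
      z <- logits[i, ] / temperature
      z <- z - max(z)
      p <- exp(z) / sum(exp(z))
      seqs[i] <- sample(AA_ALPHABET, 1L, prob = p)
    }
    out[s] <- paste(seqs, collapse = "")
  }
  design_record(id, probs, out, temperature = temperature, seed = seed)
}
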