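#' Perplexity of predicted distributions
#'
#' Exponentiated dataset-pooled mean negative log probability assigned to
#' the native residues: pooling runs over all residues of all structures
#' (double sum over structures and positions).  1 is perfect; 20 is the
#' uniform baseline.
#'
#' @param predictions a single L x 20 probability matrix or a list of them.
#' @param natives native sequence string, or list matching `predictions`.
#' @param masks optional logical vector/list; positions included.
#' @return Scalar perplexity.
#' @export
perplexity <- function(predictions, natives, masks = NULL) {
  if (is.matrix(predictions)) predictions <- list(predictions)
  if (is.character(natives) && length(natives) == 1 && !is.list(natives))
    natives <- as.list(natives)
  if (!is.null(masks) && !is.list(masks)) masks <- list(masks)
  nll <- 0; n <- 0L
  for (s in seq_along(predictions)) {
    P <- predictions[[s]]
    idx <- seq_to_idx(natives[[s]])
    ok <- !is.na(idx) & apply(is.finite(P), 1, all)
    if (!is.null(masks)) ok <- ok & masks[[s]]
    p_nat <- P[cbind(seq_len(nrow(P)), idx)][ok]
    if (any(p_nat < 1e-12)) {
      warning("zero probability on a native residue; clamped at 1e-12")
      p_nat <- pmax(p_nat, 1e-12)
    }
    nll <- nll + sum(-log(p_nat))
    n <- n + sum(ok)
  }
  if (n == 0L) stop("no residues to evaluate")
  exp(nll / n)
}

#' Sequence recovery
#'
#' Percentage of unmasked positions where the designed residue equals the
#' native residue.  Dataset summaries report the median over structures
#' (and, separately, the residue-pooled value).
#'
#' @param designed,native equal-length sequence strings.
#' @param mask optional logical vector of positions to count.
#' @return Recovery in percent.
#' @export
recovery <- function(designed, native, mask = NULL) {
  d <- strsplit(designed, "")[[1L]]
  n <- strsplit(native, "")[[1L]]
  if (length(d) != length(n)) stop("sequence lengths differ")
  ok <- n %in% AA_ALPHABET & d != "X"
  if (!is.null(mask)) ok <- ok & mask
  if (!any(ok)) stop("no unmasked residues to compare")
  100 * sum(d[ok] == n[ok]) / sum(ok)
}

#' Amino-acid composition deviation
#'
#' Relative deviation `|X - X'| / X` per amino-acid type between the pooled
#' native frequencies X and pooled designed frequencies X', with the median
#' over types present in the natives as the summary.  Types absent from the
#' natives are flagged `NA`, not divided by zero.
#'
#' @param natives,designs character vectors of sequences (pooled).
#' @return List with `native_freq`, `design_freq`, `rel_dev` (length-20
#'   named vectors) and `median_rel_dev`.
#' @export
composition_deviation <- function(natives, designs) {
  count20 <- function(seqs) {
    ch <- unlist(strsplit(seqs, ""), use.names = FALSE)
    tab <- table(factor(ch[ch %in% AA_ALPHABET], levels = AA_ALPHABET))
    as.numeric(tab)
  }
  cn <- count20(natives); cd <- count20(designs)
  if (sum(cn) == 0 || sum(cd) == 0) stop("empty sequence pool")
  X <- cn / sum(cn); Xp <- cd / sum(cd)
  rel <- ifelse(X > 0, abs(X - Xp) / X, NA_real_)
  names(X) <- names(Xp) <- names(rel) <- AA_ALPHABET
  list(native_freq = X, design_freq = Xp, rel_dev = rel,
       median_rel_dev = stats::median(rel, na.rm = TRUE))
}

#' Substitution confusion matrix and log-odds vs BLOSUM62
#'
#' Pools position-wise (native, designed) residue pairs, forms the joint
#' distribution p(x, y) with a pseudocount of 1 on the pair-count table,
#' and scores `s(x, y) = log2(p(x, y) / (q(x) q(y)))` with marginals taken
#' from the joint.  The Pearson correlation of the 400 log-odds cells with
#' the BLOSUM62 integer matrix is reported.
#'
#' @param natives,designs character vectors of aligned sequences.
#' @param pseudocount added to every pair count (default 1).
#' @return List with `counts`, `joint`, `logodds` (20 x 20 matrices) and
#'   `pearson_vs_blosum62`.
#' @export
confusion_logodds <- function(natives, designs, pseudocount = 1) {
  if (length(natives) != length(designs)) stop("pool sizes differ")
  nn <- unlist(strsplit(natives, ""), use.names = FALSE)
  dd <- unlist(strsplit(designs, ""), use.names = FALSE)
  if (length(nn) != length(dd)) stop("pooled lengths differ")
  ok <- nn %in% AA_ALPHABET & dd %in% AA_ALPHABET
  if (!any(ok)) stop("no residue pairs to pool")
  counts <- table(factor(nn[ok], levels = AA_ALPHABET),
                  factor(dd[ok], levels = AA_ALPHABET))
  counts <- matrix(as.numeric(counts), 20, 20,
                   dimnames = list(AA_ALPHABET, AA_ALPHABET))
  padded <- counts + pseudocount
  p <- padded / sum(padded)
  qx <- rowSums(p); qy <- colSums(p)
  s <- log2(p / outer(qx, qy))
  B <- blosum62()
  r <- if (stats::sd(s) > 0) stats::cor(as.vector(s), as.vector(B))
       else NA_real_   # degenerate constant matrix (e.g. exact independence)
  list(counts = counts, joint = p, logodds = s, pearson_vs_blosum62 = r)
}

#' Probability-weighted BLOSUM score
#'
#' Per residue, the BLOSUM62 row of the native residue weighted by the
#' predicted probabilities, averaged over the structure; the relative score
#' divides by the same quantity under one-hot native predictions (the mean
#' native self-substitution score), so native predictions score exactly 1.
#'
#' @param predictions L x 20 probability matrix or list of them.
#' @param natives native sequence string or list.
#' @return List with per-structure `absolute` and `relative` vectors and
#'   their medians.
#' @export
blosum_score <- function(predictions, natives) {
  if (is.matrix(predictions)) predictions <- list(predictions)
  if (!is.list(natives)) natives <- as.list(natives)
  B <- blosum62()
  abs_s <- rel_s <- numeric(length(predictions))
  for (s in seq_along(predictions)) {
    P <- predictions[[s]]
    idx <- seq_to_idx(natives[[s]])
    ok <- !is.na(idx) & apply(is.finite(P), 1, all)
    if (!any(ok)) stop("no scorable residues in structure ", s)
    scores <- rowSums(P[ok, , drop = FALSE] * B[idx[ok], , drop = FALSE])
    self <- diag(B)[idx[ok]]
    abs_s[s] <- mean(scores)
    rel_s[s] <- mean(scores) / mean(self)
  }
  list(absolute = abs_s, relative = rel_s,
       median_absolute = stats::median(abs_s),
       median_relative = stats::median(rel_s))
}

#' Hydrophobicity conservation
#'
#' Percentage of positions whose designed residue falls in the same
#' hydrophobicity class (hydrophobic vs hydrophilic) as the native residue;
#' the joint value is the headline, with a per-class breakdown over native
#' hydrophobic and native hydrophilic positions.
#'
#' @param native,designed equal-length sequence strings.
#' @param mask optional logical vector.
#' @return List with `joint`, `hydrophobic`, `hydrophilic` (percent).
#' @export
hydrophobic_conservation <- function(native, designed, mask = NULL) {
  cls <- hydrophobicity_classes()
  n <- strsplit(native, "")[[1L]]
  d <- strsplit(designed, "")[[1L]]
  if (length(n) != length(d)) stop("sequence lengths differ")
  ok <- n %in% AA_ALPHABET & d %in% AA_ALPHABET
  if (!is.null(mask)) ok <- ok & mask
  same <- cls[n] == cls[d]
  pct <- function(sel) if (any(sel)) 100 * sum(same[sel]) / sum(sel) else NA_real_
  list(joint = pct(ok),
       hydrophobic = pct(ok & cls[n] == "hydrophobic"),
       hydrophilic = pct(ok & cls[n] == "hydrophilic"))
}
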