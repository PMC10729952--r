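#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA by the sphere-point method: each atom's solvent-expanded
#' sphere (van der Waals radius + probe) is sampled with a deterministic
#' golden-spiral point set; points buried inside any neighboring sphere are
#' removed and the exposed fraction scales the sphere area.  Atoms used are
#' the four backbone heavy atoms plus the virtual C-beta as a minimal
#' side-chain proxy.
#'
#' @param x a [backbone].
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere sample points per atom (default 192).
#' @return Numeric vector: SASA per residue (Angstrom^2, `NA` if masked).
#' @export
residue_sasa <- function(x, probe = 1.4, n_points = 192L) {
  stopifnot(inherits(x, "backbone"))
  keep <- which(x$mask)
  cb <- virtual_cbeta(x)
  coords <- rbind(x$n[keep, , drop = FALSE], x$ca[keep, , drop = FALSE],
                  x$c[keep, , drop = FALSE], x$o[keep, , drop = FALSE],
                  cb[keep, , drop = FALSE])
  radii <- rep(ATOM_RADII[c("N", "CA", "C", "O", "CB")], each = length(keep))
  res_of <- rep(keep, times = 5L)
  # golden-spiral unit sphere points (deterministic)
  k <- seq_len(n_points)
  zc <- (2 * k - 1) / n_points - 1
  theta <- pi * (3 - sqrt(5)) * k
  sp <- cbind(sqrt(1 - zc^2) * cos(theta), sqrt(1 - zc^2) * sin(theta), zc)
  n_atoms <- nrow(coords)
  R <- radii + probe
  sasa_atom <- numeric(n_atoms)
  for (a in seq_len(n_atoms)) {
    pts <- sweep(sp * R[a], 2, coords[a, ], "+")
    d2 <- rowSums(sweep(coords, 2, coords[a, ], "-")^2)
    nb <- which(d2 > 0 & d2 < (R + R[a])^2)
    exposed <- rep(TRUE, n_points)
    for (b in nb) {
      hit <- rowSums(sweep(pts, 2, coords[b, ], "-")^2) < R[b]^2
      exposed <- exposed & !hit
      if (!any(exposed)) break
    }
    sasa_atom[a] <- 4 * pi * R[a]^2 * sum(exposed) / n_points
  }
  out <- rep(NA_real_, x$length)
  out[keep] <- 0
  for (a in seq_len(n_atoms)) out[res_of[a]] <- out[res_of[a]] + sasa_atom[a]
  out
}

#' Core / surface classification by relative solvent accessibility
#'
#' RSA = residue SASA divided by the theoretical maximum accessibility of
#' the residue type; residues with RSA strictly below 0.2 are core, all
#' others surface (so RSA exactly 0.2 is surface).  Unknown residue types
#' are excluded with a warning.
#'
#' @param x a [backbone].
#' @param sequence residue types (defaults to the native sequence).
#' @param rsa_cut core threshold (default 0.2).
#' @return Data frame with columns `residue`, `aa`, `sasa`, `rsa`, `class`.
#' @export
rsa_classify <- function(x, sequence = NULL, rsa_cut = 0.2) {
  stopifnot(inherits(x, "backbone"))
  if (is.null(sequence)) sequence <- x$native_seq
  if (is.null(sequence)) stop("a sequence is required for RSA normalization")
  aa <- strsplit(sequence, "")[[1L]]
  if (length(aa) != x$length) stop("sequence length must equal L")
  maxasa <- max_asa_table()
  sasa <- residue_sasa(x)
  rsa <- rep(NA_real_, x$length)
  known <- aa %in% names(maxasa)
  if (any(!known & x$mask))
    warning("unknown residue types excluded from RSA: ",
            paste(unique(aa[!known & x$mask]), collapse = ","))
  rsa[known] <- sasa[known] / maxasa[aa[known]]
  cls <- ifelse(is.na(rsa), NA_character_,
                ifelse(rsa < rsa_cut, "core", "surface"))
  data.frame(residue = seq_len(x$length), aa = aa, sasa = sasa,
             rsa = rsa, class = cls)
}

kabsch_fit <- function(P, Q) {
  # proper rotation R and translation mapping Q onto P (least squares)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Qc, Pc))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  list(R = R, t = cp - cq %*% R)
}

apply_fit <- function(Q, fit) sweep(Q %*% fit$R, 2, fit$t, "+")

#' Optimal-superposition RMSD of C-alpha traces
#'
#' Least-squares superposition (proper rotation enforced via SVD sign
#' correction) followed by the root-mean-square C-alpha deviation.
#'
#' @param P,Q L x 3 coordinate matrices (L >= 3).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(P, Q) {
  P <- as_coord_matrix(P); Q <- as_coord_matrix(Q)
  if (nrow(P) != nrow(Q)) stop("coordinate sets differ in length")
  if (nrow(P) < 3L) stop("need at least 3 atoms")
  Qs <- apply_fit(Q, kabsch_fit(P, Q))
  sqrt(mean(rowSums((P - Qs)^2)))
}

#' Global distance test (total score)
#'
#' Mean over the distance cutoffs 1, 2, 4 and 8 Angstrom of the largest
#' percentage of C-alpha pairs superposable within the cutoff.  The
#' superposition search is a documented approximation of the full
#' local-global alignment: the all-atom least-squares fit plus a fit seeded
#' from every contiguous 7-residue window, each refined by iteratively
#' re-fitting on the residues currently within the cutoff.
#'
#' @param P,Q L x 3 C-alpha coordinate matrices.
#' @param cutoffs distance cutoffs in Angstrom.
#' @param seed_len seed window length (default 7).
#' @param max_iter refinement iterations per seed (default 5).
#' @return Score in \[0, 100\].
#' @export
gdt_ts <- function(P, Q, cutoffs = c(1, 2, 4, 8), seed_len = 7L,
                   max_iter = 5L) {
  P <- as_coord_matrix(P); Q <- as_coord_matrix(Q)
  if (nrow(P) != nrow(Q)) stop("coordinate sets differ in length")
  L <- nrow(P)
  seeds <- list(seq_len(L))
  if (L >= seed_len)
    for (s in seq_len(L - seed_len + 1L))
      seeds[[length(seeds) + 1L]] <- s:(s + seed_len - 1L)
  best <- stats::setNames(numeric(length(cutoffs)), cutoffs)
  for (sel0 in seeds) {
    if (length(sel0) < 3L) next
    for (ci in seq_along(cutoffs)) {
      cut <- cutoffs[ci]
      sel <- sel0
      for (it in seq_len(max_iter)) {
        fit <- kabsch_fit(P[sel, , drop = FALSE], Q[sel, , drop = FALSE])
        d <- sqrt(rowSums((P - apply_fit(Q, fit))^2))
        new_sel <- which(d <= cut)
        frac <- length(new_sel) / L
        if (frac > best[ci]) best[ci] <- frac
        if (length(new_sel) < 3L || identical(new_sel, sel)) break
        sel <- new_sel
      }
    }
  }
  100 * mean(best)
}

#' Evaluate a set of designs against natives
#'
#' Aggregates the full sequence-quality battery for a dataset of
#' native/designed pairs: per-structure recovery, hydrophobicity
#' conservation and low-complexity fraction, plus pooled perplexity (when
#' probabilities are given), BLOSUM scores, composition deviation and the
#' substitution log-odds correlation.  When structures are supplied,
#' recovery is additionally split into core and surface residues by RSA.
#'
#' @param natives character vector of native sequences.
#' @param designs character vector of designed sequences (same lengths).
#' @param predictions optional list of L x 20 probability matrices.
#' @param structures optional list of [backbone] objects for the RSA split.
#' @return List with `per_structure` (data frame) and `aggregate` (list).
#' @export
evaluate_designs <- function(natives, designs, predictions = NULL,
                             structures = NULL) {
  stopifnot(length(natives) == length(designs))
  S <- length(natives)
  per <- data.frame(structure = seq_len(S),
                    recovery = NA_real_, hydro_joint = NA_real_,
                    lcr_native = NA_real_, lcr_design = NA_real_,
                    core_recovery = NA_real_, surface_recovery = NA_real_)
  for (s in seq_len(S)) {
    per$recovery[s] <- recovery(designs[s], natives[s])
    per$hydro_joint[s] <- hydrophobic_conservation(natives[s], designs[s])$joint
    per$lcr_native[s] <- seg_lcr(natives[s])$lcr
    per$lcr_design[s] <- seg_lcr(designs[s])$lcr
    if (!is.null(structures)) {
      cls <- rsa_classify(structures[[s]], natives[s])$class
      for (what in c("core", "surface")) {
        sel <- !is.na(cls) & cls == what
        if (sum(sel) > 0)
          per[[paste0(what, "_recovery")]][s] <-
            recovery(designs[s], natives[s], mask = sel)
      }
    }
  }
  comp <- composition_deviation(natives, designs)
  conf <- confusion_logodds(natives, designs)
  agg <- list(median_recovery = stats::median(per$recovery),
              pooled_recovery = {
                nn <- unlist(strsplit(natives, "")); dd <- unlist(strsplit(designs, ""))
                ok <- nn %in% AA_ALPHABET & dd != "X"
                100 * sum(nn[ok] == dd[ok]) / sum(ok)
              },
              median_rel_dev = comp$median_rel_dev,
              pearson_vs_blosum62 = conf$pearson_vs_blosum62,
              median_hydro = stats::median(per$hydro_joint),
              mean_lcr_native = mean(per$lcr_native),
              mean_lcr_design = mean(per$lcr_design))
  if (!is.null(predictions)) {
    agg$perplexity <- perplexity(predictions, as.list(natives))
    bs <- blosum_score(predictions, as.list(natives))
    agg$median_blosum <- bs$median_absolute
    agg$median_rel_blosum <- bs$median_relative
  }
  list(per_structure = per, aggregate = agg,
       composition = comp, confusion = conf)
}

#' Write an evaluation report
#'
#' Writes the per-structure table as TSV and the aggregate statistics as
#' JSON.
#'
#' @param report result of [evaluate_designs()].
#' @param tsv_path,json_path output paths (`NULL` to skip one).
#' @return Invisibly, `report`.
#' @export
write_metrics_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(report$per_structure, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report$aggregate, json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(report)
}
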