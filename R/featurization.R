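#' Per-residue local frames
#'
#' Builds the orthonormal right-handed basis `Q = [b, n, b x n]` with
#' `b = (u - v)/||u - v||` and `n = (u x v)/||u x v||`, where
#' `u = r_Ca - r_N` and `v = r_C - r_Ca`.  All node and edge vector
#' features are expressed in these frames, which is what makes the
#' featurization rotation- and translation-invariant.
#'
#' Degenerate geometry (`||u - v||` or `||u x v||` below 1e-8) yields an
#' identity frame and a degeneracy flag.
#'
#' @param x a [backbone].
#' @return List with `Q` (L x 3 x 3 array; `Q[i,,]` has columns b, n, bxn)
#'   and `degenerate` (logical vector).
#' @export
local_frames <- function(x) {
  stopifnot(inherits(x, "backbone"))
  L <- x$length
  u <- x$ca - x$n
  v <- x$c - x$ca
  Q <- array(NA_real_, c(L, 3, 3))
  degenerate <- logical(L)
  for (i in seq_len(L)) {
    if (!x$mask[i]) { degenerate[i] <- NA; next }
    b <- u[i, ] - v[i, ]
    w <- cross3(u[i, ], v[i, ])
    nb <- sqrt(sum(b^2)); nw <- sqrt(sum(w^2))
    if (nb < 1e-8 || nw < 1e-8) {
      Q[i, , ] <- diag(3)
      degenerate[i] <- TRUE
      next
    }
    b <- b / nb; n <- w / nw
    Q[i, , ] <- cbind(b, n, cross3(b, n))
  }
  list(Q = Q, degenerate = degenerate)
}

#' Gaussian radial basis encoding of a distance
#'
#' Encodes distances with 16 Gaussian bumps whose centers are evenly spaced
#' on \[2, 22\] Angstrom and whose width equals the center spacing (the
#' convention of the cited message-passing design networks).
#'
#' @param d numeric vector of distances (Angstrom, >= 0).
#' @param n_bins number of basis functions (default 16).
#' @param d_min,d_max center range in Angstrom.
#' @return length(d) x n_bins matrix.
#' @export
rbf_encode <- function(d, n_bins = 16L, d_min = 2, d_max = 22) {
  centers <- seq(d_min, d_max, length.out = n_bins)
  sigma <- (d_max - d_min) / (n_bins - 1)
  z <- outer(d, centers, function(a, c) ((a - c) / sigma)^2)
  exp(-z)
}

#' Sinusoidal encoding of a sequence offset
#'
#' Standard sinusoidal positional encoding of the signed residue-index
#' difference i - j: 8 geometric frequencies, `sin` components first, then
#' `cos`.  Offsets are signed and unclipped.
#'
#' @param offset integer vector of signed offsets.
#' @param dim encoding dimension (even; default 16).
#' @return length(offset) x dim matrix with entries in \[-1, 1\].
#' @export
positional_encode <- function(offset, dim = 16L) {
  stopifnot(dim %% 2 == 0)
  k <- seq_len(dim / 2) - 1
  freq <- 1 / (10000^(2 * k / dim))
  ang <- outer(as.numeric(offset), freq)
  cbind(sin(ang), cos(ang))
}

#' Relative orientation quaternion
#'
#' Unit quaternion (w, x, y, z) of the relative rotation `t(Q_i) %*% Q_j`
#' (frame j expressed in frame i), with the sign fixed by w >= 0 (first
#' nonzero component positive when w = 0).
#'
#' @param Qi,Qj orthonormal 3 x 3 frames.
#' @return Numeric length-4 unit quaternion.
#' @export
relative_quaternion <- function(Qi, Qj) {
  rotmat_to_quat(crossprod(Qi, Qj))
}

rotmat_to_quat <- function(R) {
  # Shepperd's method: pick the largest of the four squared components
  t0 <- 1 + R[1, 1] + R[2, 2] + R[3, 3]
  t1 <- 1 + R[1, 1] - R[2, 2] - R[3, 3]
  t2 <- 1 - R[1, 1] + R[2, 2] - R[3, 3]
  t3 <- 1 - R[1, 1] - R[2, 2] + R[3, 3]
  m <- which.max(c(t0, t1, t2, t3))
  if (m == 1) {
    s <- sqrt(t0) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (m == 2) {
    s <- sqrt(t1) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (m == 3) {
    s <- sqrt(t2) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(t3) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  q <- q / sqrt(sum(q^2))
  # canonical sign: w >= 0, tie broken by first nonzero component
  nz <- which(abs(q) > 1e-12)
  if (length(nz) > 0 && q[nz[1]] < 0) q <- -q
  if (q[1] < 0) q <- -q
  q
}

quat_to_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Virtual-atom parameters
#'
#' Learnable coefficients of the three virtual atoms: each atom n is placed
#' at `r_V = x_n u + y_n v + z_n (u x v) + r_Ca` with the constraint
#' `x^2 + y^2 + z^2 = 1` enforced by projection onto the unit sphere on
#' every evaluation.  Initialization is uniform on the sphere under a
#' deterministic seed.
#'
#' @param n_atoms number of virtual atoms (default 3).
#' @param seed integer seed.
#' @return n_atoms x 3 matrix of unit-norm coefficient rows.
#' @export
virtual_atom_init <- function(n_atoms = 3L, seed = 1L) {
  set.seed(seed)
  p <- matrix(stats::rnorm(3 * n_atoms), n_atoms, 3)
  normalize_va(p)
}

normalize_va <- function(params) {
  nr <- sqrt(rowSums(params^2))
  if (any(nr < 1e-12)) stop("virtual-atom parameter rows must be nonzero")
  params / nr
}

#' Virtual atom positions
#'
#' Places the learnable virtual atoms of every unmasked residue by the
#' linear combination `r_V = x u + y v + z (u x v) + r_Ca` after projecting
#' the coefficient rows onto the unit sphere.
#'
#' @param params n_atoms x 3 coefficient matrix (see [virtual_atom_init()]).
#' @param x a [backbone].
#' @return L x n_atoms x 3 array (`NA` at masked residues).
#' @export
virtual_atom_positions <- function(params, x) {
  stopifnot(inherits(x, "backbone"))
  params <- normalize_va(params)
  u <- x$ca - x$n
  v <- x$c - x$ca
  w <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  L <- x$length
  out <- array(NA_real_, c(L, nrow(params), 3))
  for (a in seq_len(nrow(params))) {
    pos <- params[a, 1] * u + params[a, 2] * v + params[a, 3] * w + x$ca
    pos[!x$mask, ] <- NA_real_
    out[, a, ] <- pos
  }
  out
}

dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

bond_angle <- function(a, b, c) {
  # angle at b between vectors b->a and b->c
  v1 <- a - b; v2 <- c - b
  acos(pmin(1, pmax(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
}

#' Node features
#'
#' Per-residue invariant features, concatenated as:
#' \itemize{
#'   \item 12 dims: unit vectors from C-alpha to N, C, O and the virtual
#'     C-beta, expressed in the residue's local frame;
#'   \item 12 dims: sin/cos of the three backbone bond angles
#'     (C(i-1)-N-Ca, N-Ca-C, Ca-C-N(i+1)) and the three torsions
#'     (omega, phi, psi);
#'   \item 64 dims: RBF-encoded distances from C-alpha to N, C, O and the
#'     virtual C-beta (4 x 16).
#' }
#' Angle features that need residue i-1 or i+1 (chain termini or a masked
#' neighbor) are zero-filled for both sin and cos.  The resulting dimension
#' (88) is recorded in the attribute `dim`.
#'
#' @param x a [backbone].
#' @param frames output of [local_frames()] (computed if `NULL`).
#' @return L x 88 matrix (masked rows `NA`) with attribute `dim`.
#' @export
node_features <- function(x, frames = NULL) {
  stopifnot(inherits(x, "backbone"))
  if (is.null(frames)) frames <- local_frames(x)
  L <- x$length
  cb <- virtual_cbeta(x)
  targets <- list(x$n, x$c, x$o, cb)
  vec_feat <- matrix(NA_real_, L, 12)
  dist_feat <- matrix(NA_real_, L, 64)
  ang_feat <- matrix(NA_real_, L, 12)
  for (i in seq_len(L)) {
    if (!x$mask[i]) next
    Qi <- frames$Q[i, , ]
    vv <- numeric(0); dd <- numeric(0)
    for (tgt in targets) {
      dvec <- tgt[i, ] - x$ca[i, ]
      dn <- sqrt(sum(dvec^2))
      vv <- c(vv, if (dn > 1e-12) crossprod(Qi, dvec)[, 1] / dn else c(0, 0, 0))
      dd <- c(dd, dn)
    }
    vec_feat[i, ] <- vv
    dist_feat[i, ] <- as.vector(t(rbf_encode(dd)))
    prev_ok <- i > 1L && x$mask[i - 1L]
    next_ok <- i < L && x$mask[i + 1L]
    angles <- rep(NA_real_, 6)   # theta1, theta2, theta3, omega, phi, psi
    angles[2] <- bond_angle(x$n[i, ], x$ca[i, ], x$c[i, ])
    if (prev_ok) {
      angles[1] <- bond_angle(x$c[i - 1L, ], x$n[i, ], x$ca[i, ])
      angles[4] <- dihedral(x$ca[i - 1L, ], x$c[i - 1L, ], x$n[i, ], x$ca[i, ])
      angles[5] <- dihedral(x$c[i - 1L, ], x$n[i, ], x$ca[i, ], x$c[i, ])
    }
    if (next_ok) {
      angles[3] <- bond_angle(x$ca[i, ], x$c[i, ], x$n[i + 1L, ])
      angles[6] <- dihedral(x$n[i, ], x$ca[i, ], x$c[i, ], x$n[i + 1L, ])
    }
    sc <- as.vector(rbind(sin(angles), cos(angles)))
    sc[is.na(sc)] <- 0   # termini / masked neighbors: inert zero fill
    ang_feat[i, ] <- sc
  }
  out <- cbind(vec_feat, ang_feat, dist_feat)
  attr(out, "dim_meta") <- c(vectors = 12L, angles = 12L, distances = 64L,
                             total = 88L)
  out
}

# Stack the 8 per-residue atom positions used by edge distance features:
# Ca, C, N, O, virtual Cb, then the 3 learnable virtual atoms.
edge_atom_stack <- function(x, va_params) {
  cb <- virtual_cbeta(x)
  va <- virtual_atom_positions(va_params, x)
  L <- x$length
  A <- array(NA_real_, c(L, 8, 3))
  A[, 1, ] <- x$ca; A[, 2, ] <- x$c; A[, 3, ] <- x$n
  A[, 4, ] <- x$o;  A[, 5, ] <- cb
  A[, 6, ] <- va[, 1, ]; A[, 7, ] <- va[, 2, ]; A[, 8, ] <- va[, 3, ]
  A
}

#' Edge features
#'
#' Per-edge invariant features for every directed edge (j -> i) of the
#' graph, concatenated as:
#' \itemize{
#'   \item 75 dims: unit vectors from each of the 5 backbone atoms
#'     (Ca, C, N, O, virtual Cb) of residue j to each of the 5 of residue i,
#'     rotated into the local frame of i (25 vectors x 3);
#'   \item 1024 dims: RBF encodings of the 64 interatomic distances between
#'     the 8 atoms of i and the 8 atoms of j (5 backbone + 3 learnable
#'     virtual atoms);
#'   \item 4 dims: the relative-orientation quaternion from frame j to
#'     frame i;
#'   \item 16 dims: sinusoidal encoding of the signed sequence offset i - j.
#' }
#' Total dimension 1119 under the defaults.
#'
#' @param x a [backbone].
#' @param graph a `contact_graph` over `x`.
#' @param frames output of [local_frames()] (computed if `NULL`).
#' @param va_params virtual-atom coefficients (default deterministic
#'   initialization).
#' @return E x 1119 matrix with attribute `dim_meta` giving the block
#'   layout.
#' @export
edge_features <- function(x, graph, frames = NULL,
                          va_params = virtual_atom_init()) {
  stopifnot(inherits(x, "backbone"), inherits(graph, "contact_graph"))
  if (is.null(frames)) frames <- local_frames(x)
  st <- edge_static_blocks(x, graph, frames)
  A <- edge_atom_stack(x, va_params)
  dist_rbf <- edge_dist_block(A, graph$src, graph$dst)
  out <- cbind(st$uv, dist_rbf, st$quat, st$pe)
  attr(out, "dim_meta") <- c(unit_vectors = 75L, distances = 1024L,
                             quaternion = 4L, positional = 16L,
                             total = 1119L)
  out
}

# Parameter-independent edge feature blocks: the 25 inter-residue unit
# vectors in the target frame, the relative quaternion and the sequence
# positional encoding.
edge_static_blocks <- function(x, graph, frames) {
  A <- edge_atom_stack(x, virtual_atom_init())   # only atoms 1..5 used
  E <- length(graph$src)
  uv <- matrix(0, E, 75)
  quat <- matrix(0, E, 4)
  src <- graph$src; dst <- graph$dst
  for (e in seq_len(E)) {
    i <- dst[e]; j <- src[e]
    Qi <- frames$Q[i, , ]
    col <- 0L
    vals <- numeric(75)
    for (ai in 1:5) for (aj in 1:5) {
      dvec <- A[i, ai, ] - A[j, aj, ]
      dn <- sqrt(sum(dvec^2))
      vals[col + 1:3] <- if (dn > 1e-12) crossprod(Qi, dvec)[, 1] / dn else 0
      col <- col + 3L
    }
    uv[e, ] <- vals
    quat[e, ] <- relative_quaternion(Qi, frames$Q[j, , ])
  }
  list(uv = uv, quat = quat, pe = positional_encode(dst - src))
}

# RBF encodings of all 8x8 interatomic distances, vectorized over edges.
edge_dist_block <- function(A, src, dst) {
  E <- length(src)
  dist_rbf <- matrix(0, E, 1024)
  col <- 0L
  for (ai in 1:8) for (aj in 1:8) {
    dd <- sqrt(rowSums(matrix(A[dst, ai, ] - A[src, aj, ], ncol = 3)^2))
    dist_rbf[, col + 1:16] <- rbf_encode(dd)
    col <- col + 16L
  }
  dist_rbf
}

#' Serialize a feature bundle
#'
#' Writes the node and edge feature matrices as gzip-compressed TSV
#' arrays together with a JSON configuration echo (cutoff, dimensions,
#' virtual-atom coefficients), so a featurization can be reproduced and
#' compared exactly.
#'
#' @param x a [backbone].
#' @param graph a `contact_graph` over `x`.
#' @param prefix output path prefix; writes `<prefix>.node.tsv.gz`,
#'   `<prefix>.edge.tsv.gz` and `<prefix>.config.json`.
#' @param va_params virtual-atom coefficients.
#' @return The three paths, invisibly.
#' @export
write_feature_bundle <- function(x, graph, prefix,
                                 va_params = virtual_atom_init()) {
  nf <- node_features(x)
  ef <- edge_features(x, graph, va_params = va_params)
  paths <- paste0(prefix, c(".node.tsv.gz", ".edge.tsv.gz", ".config.json"))
  for (i in 1:2) {
    con <- gzfile(paths[i], "w")
    utils::write.table(if (i == 1) nf else ef, con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    close(con)
  }
  jsonlite::write_json(
    list(format = "cgraphdesign-features-1",
         graph = list(mode = graph$mode, cutoff = graph$cutoff, k = graph$k),
         node_dim = ncol(nf), edge_dim = ncol(ef),
         n_nodes = x$length, n_edges = length(graph$src),
         va_params = normalize_va(va_params)),
    paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
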