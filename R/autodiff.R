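# Tape-based reverse-mode automatic differentiation over dense matrices.
#
# The network in this package is trained with plain R matrix algebra; this
# file provides the minimal operator set the architecture needs (affine
# maps, GELU, layer norm, gather/scatter, segment and column softmax,
# selective-kernel mixing, dropout, cross-entropy).  Every op appends a
# node to a tape; ad_backward() walks the tape once in reverse.  Values are
# matrices throughout; parameters carry their gradient on the node after
# the backward pass.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 512L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_accum <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

# Leaves ---------------------------------------------------------------

ad_const <- function(tape, value) ad_node(tape, value)

ad_param <- function(tape, value) ad_node(tape, value)   # grad read after backward

# Core ops -------------------------------------------------------------

# y = x W + b  (b is a plain numeric vector of length ncol(W))
ad_linear <- function(tape, x, W, b) {
  val <- x$value %*% W$value
  val <- val + matrix(b$value, nrow(val), ncol(val), byrow = TRUE)
  ad_node(tape, val, backward = function(g, nd) {
    ad_accum(x, g %*% t(W$value))
    ad_accum(W, crossprod(x$value, g))
    ad_accum(b, colSums(g))
  })
}

# smooth gating nonlinearity: x * sigmoid(1.702 x), the fast sigmoid form
# of the Gaussian-error linear unit
ad_gelu <- function(tape, x) {
  xv <- x$value
  s <- 1 / (1 + exp(-1.702 * xv))
  ad_node(tape, xv * s, backward = function(g, nd) {
    ad_accum(x, g * (s + 1.702 * xv * s * (1 - s)))
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, backward = function(g, nd) {
    ad_accum(a, g); ad_accum(b, g)
  })
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, backward = function(g, nd) {
    ad_accum(a, g * b$value); ad_accum(b, g * a$value)
  })
}

ad_scale <- function(tape, x, s) {
  ad_node(tape, x$value * s, backward = function(g, nd) ad_accum(x, g * s))
}

ad_concat <- function(tape, parts) {
  widths <- vapply(parts, function(p) ncol(p$value), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_node(tape, do.call(cbind, lapply(parts, function(p) p$value)),
          backward = function(g, nd) {
            for (k in seq_along(parts))
              ad_accum(parts[[k]], g[, starts[k]:ends[k], drop = FALSE])
          })
}

ad_gather <- function(tape, x, idx) {
  n <- nrow(x$value)
  ad_node(tape, x$value[idx, , drop = FALSE], backward = function(g, nd) {
    ad_accum(x, scatter_rows(g, idx, n))
  })
}

scatter_rows <- function(g, idx, n) {
  out <- matrix(0, n, ncol(g))
  rs <- rowsum(g, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

ad_scatter_sum <- function(tape, x, idx, n_out) {
  ad_node(tape, scatter_rows(x$value, idx, n_out), backward = function(g, nd) {
    ad_accum(x, g[idx, , drop = FALSE])
  })
}

# rowwise scale: y[e, ] = x[e, ] * s[e]  with s an E x 1 node
ad_rowscale <- function(tape, x, s) {
  sv <- s$value[, 1L]
  ad_node(tape, x$value * sv, backward = function(g, nd) {
    ad_accum(x, g * sv)
    ad_accum(s, matrix(rowSums(g * x$value), ncol = 1L))
  })
}

# rowwise scale by a constant vector (e.g. 1/|shared neighbors|)
ad_rowscale_const <- function(tape, x, v) {
  ad_node(tape, x$value * v, backward = function(g, nd) ad_accum(x, g * v))
}

ad_rowsum <- function(tape, x) {
  ad_node(tape, matrix(rowSums(x$value), ncol = 1L), backward = function(g, nd) {
    ad_accum(x, matrix(g[, 1L], nrow(x$value), ncol(x$value)))
  })
}

ad_colsum <- function(tape, x) {
  ad_node(tape, matrix(colSums(x$value), nrow = 1L), backward = function(g, nd) {
    ad_accum(x, matrix(g, nrow(x$value), ncol(x$value), byrow = TRUE))
  })
}

ad_broadcast_row <- function(tape, x, n) {
  ad_node(tape, matrix(x$value, n, ncol(x$value), byrow = TRUE),
          backward = function(g, nd) {
            ad_accum(x, matrix(colSums(g), nrow = 1L))
          })
}

ad_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  mu <- rowMeans(xv)
  xc <- xv - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  gv <- gamma$value
  val <- sweep(xhat, 2, gv, "*")
  val <- val + matrix(beta$value, nrow(val), ncol(val), byrow = TRUE)
  ad_node(tape, val, backward = function(g, nd) {
    dxhat <- sweep(g, 2, gv, "*")
    ad_accum(gamma, colSums(g * xhat))
    ad_accum(beta, colSums(g))
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    ad_accum(x, inv * (dxhat - m1 - xhat * m2))
  })
}

# softmax of a score column within groups (attention over in-neighbors)
ad_segment_softmax <- function(tape, scores, groups) {
  s <- scores$value[, 1L]
  mx <- stats::ave(s, groups, FUN = max)
  e <- exp(s - mx)
  den <- stats::ave(e, groups, FUN = sum)
  p <- e / den
  ad_node(tape, matrix(p, ncol = 1L), backward = function(g, nd) {
    gp <- g[, 1L]
    dot <- stats::ave(p * gp, groups, FUN = sum)
    ad_accum(scores, matrix(p * (gp - dot), ncol = 1L))
  })
}

# per-dimension softmax over all rows (global context weights)
ad_col_softmax <- function(tape, x) {
  xv <- x$value
  mx <- matrix(apply(xv, 2, max), nrow(xv), ncol(xv), byrow = TRUE)
  e <- exp(xv - mx)
  p <- sweep(e, 2, colSums(e), "/")
  ad_node(tape, p, backward = function(g, nd) {
    dot <- matrix(colSums(p * g), nrow(p), ncol(p), byrow = TRUE)
    ad_accum(x, p * (g - dot))
  })
}

# per-dimension softmax within row groups (one group per structure in a
# batched disjoint-union graph); gid must cover 1..n_groups
ad_group_col_softmax <- function(tape, x, gid, gid_split, n_groups) {
  xv <- x$value
  mx <- matrix(0, n_groups, ncol(xv))
  for (gr in seq_len(n_groups)) {
    rows <- gid_split[[gr]]
    mx[gr, ] <- if (length(rows) == 1L) xv[rows, ]
    else apply(xv[rows, , drop = FALSE], 2, max)
  }
  e <- exp(xv - mx[gid, , drop = FALSE])
  den <- rowsum(e, gid)
  p <- e / den[gid, , drop = FALSE]
  ad_node(tape, p, backward = function(g, nd) {
    dot <- rowsum(p * g, gid)
    ad_accum(x, p * (g - dot[gid, , drop = FALSE]))
  })
}

# column sums within row groups: returns an n_groups x d matrix
ad_group_colsum <- function(tape, x, gid, n_groups) {
  ad_node(tape, rowsum(x$value, gid), backward = function(g, nd) {
    ad_accum(x, g[gid, , drop = FALSE])
  })
}

# selective-kernel mixing: per-dimension softmax weights across branches,
# merged = sum_b softmax_b(logits)[b] * branch_b
ad_sk_mix <- function(tape, logits, branches) {
  B <- length(branches)
  mx <- Reduce(pmax, lapply(logits, function(l) l$value))
  ev <- lapply(logits, function(l) exp(l$value - mx))
  den <- Reduce(`+`, ev)
  w <- lapply(ev, function(e) e / den)
  out <- Reduce(`+`, Map(function(wb, fb) wb * fb$value, w, branches))
  ad_node(tape, out, backward = function(g, nd) {
    for (b in seq_len(B)) {
      ad_accum(branches[[b]], g * w[[b]])
      ad_accum(logits[[b]], g * w[[b]] * (branches[[b]]$value - out))
    }
  })
}

ad_dropout <- function(tape, x, p) {
  if (p <= 0) return(x)
  mask <- (matrix(stats::runif(length(x$value)), nrow(x$value)) >= p) / (1 - p)
  ad_node(tape, x$value * mask, backward = function(g, nd) {
    ad_accum(x, g * mask)
  })
}

# mean categorical cross-entropy from logits (natural log, no smoothing)
ad_ce_loss <- function(tape, logits, targets) {
  lv <- logits$value
  n <- nrow(lv)
  mx <- apply(lv, 1, max)
  lse <- mx + log(rowSums(exp(lv - mx)))
  picked <- lv[cbind(seq_len(n), targets)]
  loss <- mean(lse - picked)
  ad_node(tape, matrix(loss, 1L, 1L), backward = function(g, nd) {
    P <- exp(lv - lse)
    P[cbind(seq_len(n), targets)] <- P[cbind(seq_len(n), targets)] - 1
    ad_accum(logits, (g[1L] / n) * P)
  })
}

ad_backward <- function(tape, root) {
  root$grad <- matrix(1, nrow(root$value), ncol(root$value))
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad, nd)
  }
  invisible(NULL)
}
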