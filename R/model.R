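#' Model configuration
#'
#' Configuration of the contact-graph network: a stack of `n_blocks`
#' message-passing blocks in which edge states are updated first (basic
#' update from the two endpoint states, optionally enriched by the
#' symmetric reverse edge and by second-order edges through shared
#' neighbors, merged by a selective kernel) and node states second (local
#' graph attention plus a global context branch, merged by a selective
#' kernel), each followed by residual + layer norm + feed-forward wrappers.
#' The output head emits one-shot 20-class logits per residue.
#'
#' Ablation toggles reproduce the reduced variants as pure configuration:
#' disabling `use_symmetric`/`use_soe` removes those edge branches;
#' disabling `use_sk_edges`/`use_sk_nodes` replaces the selective kernel by
#' average pooling.
#'
#' @param hidden hidden width of node and edge states (default 128).
#' @param n_blocks number of blocks (default 10).
#' @param dropout dropout probability in \[0, 1) (default 0.1).
#' @param use_symmetric include the symmetric-edge branch (contact-graph
#'   mode only).
#' @param use_soe include the second-order-edge branch.
#' @param use_sk_edges,use_sk_nodes merge branches with a selective kernel
#'   (`TRUE`) or average pooling (`FALSE`).
#' @param graph_mode `"cgraph"` or `"knn"`.
#' @param cutoff contact cutoff in Angstrom (cgraph mode).
#' @param k neighbor count (knn mode).
#' @param attention_scale scale attention logits by 1/sqrt(width)
#'   (default `FALSE`: raw dot products).
#' @param n_classes output classes (20).
#' @return An object of class `cgnn_config`.
#' @export
cgnn_config <- function(hidden = 128L, n_blocks = 10L, dropout = 0.1,
                        use_symmetric = TRUE, use_soe = TRUE,
                        use_sk_edges = TRUE, use_sk_nodes = TRUE,
                        graph_mode = c("cgraph", "knn"),
                        cutoff = 12, k = 30L,
                        attention_scale = FALSE, n_classes = 20L) {
  graph_mode <- match.arg(graph_mode)
  if (hidden < 1 || n_blocks < 1) stop("hidden and n_blocks must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (graph_mode == "knn" && use_symmetric)
    stop("symmetric edge updates require the contact graph (reverse edges ",
         "may be missing in knn mode); set use_symmetric = FALSE")
  structure(list(hidden = as.integer(hidden), n_blocks = as.integer(n_blocks),
                 dropout = dropout, use_symmetric = use_symmetric,
                 use_soe = use_soe, use_sk_edges = use_sk_edges,
                 use_sk_nodes = use_sk_nodes, graph_mode = graph_mode,
                 cutoff = cutoff, k = as.integer(k),
                 attention_scale = attention_scale,
                 n_classes = as.integer(n_classes),
                 node_dim = 88L, edge_dim = 1119L),
            class = "cgnn_config")
}

#' Ablation variant configurations
#'
#' Returns the configuration of the reduced model variants used in the
#' ablation comparisons, as pure configuration over [cgnn_config()]:
#' `"model1"` drops both symmetric and second-order edge branches,
#' `"model2"` keeps only the symmetric branch, `"model3"` only the
#' second-order branch, `"model4"` replaces all selective kernels by
#' average pooling, `"model5"` replaces only the edge-update kernels,
#' `"model6"` only the node-update kernels, and `"full"` is the default.
#'
#' @param variant one of `"full"`, `"model1"` ... `"model6"`.
#' @param ... further arguments passed to [cgnn_config()].
#' @return A `cgnn_config`.
#' @export
ablation_config <- function(variant = "full", ...) {
  switch(variant,
         full   = cgnn_config(...),
         model1 = cgnn_config(use_symmetric = FALSE, use_soe = FALSE, ...),
         model2 = cgnn_config(use_symmetric = TRUE, use_soe = FALSE, ...),
         model3 = cgnn_config(use_symmetric = FALSE, use_soe = TRUE, ...),
         model4 = cgnn_config(use_sk_edges = FALSE, use_sk_nodes = FALSE, ...),
         model5 = cgnn_config(use_sk_edges = FALSE, ...),
         model6 = cgnn_config(use_sk_nodes = FALSE, ...),
         stop("unknown variant: ", variant))
}

xavier <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

add_mlp <- function(params, name, d_in, d_hidden, d_out) {
  params[[paste0(name, ".W1")]] <- xavier(d_in, d_hidden)
  params[[paste0(name, ".b1")]] <- numeric(d_hidden)
  params[[paste0(name, ".W2")]] <- xavier(d_hidden, d_out)
  params[[paste0(name, ".b2")]] <- numeric(d_out)
  params
}

add_ln <- function(params, name, d) {
  params[[paste0(name, ".gamma")]] <- rep(1, d)
  params[[paste0(name, ".beta")]] <- numeric(d)
  params
}

add_sk <- function(params, name, d, n_branches) {
  params <- add_mlp(params, paste0(name, ".squeeze"), d, d, d)
  for (b in seq_len(n_branches))
    params <- add_mlp(params, paste0(name, ".exc", b), d, d, d)
  params
}

n_edge_branches <- function(cfg) 1L + cfg$use_symmetric + cfg$use_soe

#' Initialize a model
#'
#' Creates all parameters of the block stack under a deterministic seed:
#' Xavier-uniform affine maps, unit/zero layer norms, and the three
#' learnable virtual-atom coefficient triples initialized uniformly on the
#' unit sphere.  Every unlabeled "MLP" is two affine layers with a GELU
#' between, hidden width equal to the model width; input features enter
#' through a single affine projection plus layer norm.
#'
#' @param config a [cgnn_config()].
#' @param seed integer seed.
#' @return An object of class `cgnn_model` with elements `config`, `params`
#'   (named list of arrays) and `seed`.
#' @export
cgnn_init <- function(config = cgnn_config(), seed = 1L) {
  stopifnot(inherits(config, "cgnn_config"))
  set.seed(seed)
  w <- config$hidden
  p <- list()
  p[["va"]] <- virtual_atom_init(3L, seed = seed + 1L)
  p[["node_proj.W"]] <- xavier(config$node_dim, w)
  p[["node_proj.b"]] <- numeric(w)
  p <- add_ln(p, "node_proj.ln", w)
  p[["edge_proj.W"]] <- xavier(config$edge_dim, w)
  p[["edge_proj.b"]] <- numeric(w)
  p <- add_ln(p, "edge_proj.ln", w)
  for (l in seq_len(config$n_blocks)) {
    pre <- paste0("blk", l)
    p <- add_mlp(p, paste0(pre, ".edge.basic"), 3 * w, w, w)
    if (config$use_symmetric) p <- add_mlp(p, paste0(pre, ".edge.sym"), 2 * w, w, w)
    if (config$use_soe) p <- add_mlp(p, paste0(pre, ".edge.soe"), 3 * w, w, w)
    p <- add_mlp(p, paste0(pre, ".edge.e2"), w, w, w)
    if (config$use_sk_edges)
      p <- add_sk(p, paste0(pre, ".edge.sk"), w, n_edge_branches(config))
    p <- add_ln(p, paste0(pre, ".edge.ln1"), w)
    p <- add_mlp(p, paste0(pre, ".edge.ffn"), w, w, w)
    p <- add_ln(p, paste0(pre, ".edge.ln2"), w)
    p <- add_mlp(p, paste0(pre, ".node.q"), w, w, w)
    p <- add_mlp(p, paste0(pre, ".node.k"), w, w, w)
    p <- add_mlp(p, paste0(pre, ".node.v"), 3 * w, w, w)
    p <- add_mlp(p, paste0(pre, ".node.ga"), w, w, w)
    p <- add_mlp(p, paste0(pre, ".node.gv"), w, w, w)
    p <- add_mlp(p, paste0(pre, ".node.gout"), 2 * w, w, w)
    if (config$use_sk_nodes) p <- add_sk(p, paste0(pre, ".node.sk"), w, 2L)
    p <- add_ln(p, paste0(pre, ".node.ln1"), w)
    p <- add_mlp(p, paste0(pre, ".node.ffn"), w, w, w)
    p <- add_ln(p, paste0(pre, ".node.ln2"), w)
  }
  p[["head.W"]] <- xavier(w, config$n_classes)
  p[["head.b"]] <- numeric(config$n_classes)
  structure(list(config = config, params = p, seed = as.integer(seed)),
            class = "cgnn_model")
}

#' Parameter count
#'
#' @param model a `cgnn_model`.
#' @return Total number of scalar parameters.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' Describe a model
#'
#' Prints a layer table (parameter name, shape, count) and the total
#' parameter count.
#'
#' @param model a `cgnn_model`.
#' @return Invisibly, the layer table data frame.
#' @export
describe_model <- function(model) {
  tab <- data.frame(
    parameter = names(model$params),
    shape = vapply(model$params, function(x)
      paste(if (is.matrix(x)) dim(x) else length(x), collapse = "x"),
      character(1)),
    count = vapply(model$params, length, numeric(1)),
    row.names = NULL)
  print(tab, row.names = FALSE)
  cat(sprintf("total parameters: %s\n", format(sum(tab$count), big.mark = ",")))
  invisible(tab)
}

#' @export
print.cgnn_model <- function(x, ...) {
  cat(sprintf("<cgnn_model> width %d, %d blocks, %s parameters (%s)\n",
              x$config$hidden, x$config$n_blocks,
              format(count_params(x), big.mark = ","),
              if (x$config$graph_mode == "cgraph")
                paste0("cgraph-", x$config$cutoff)
              else paste0("knn-", x$config$k)))
  invisible(x)
}

# Precompute everything about one structure that does not depend on model
# parameters: the unmasked subgraph, static feature blocks, second-order
# edge triples, and the geometry needed by the differentiable virtual-atom
# distance block.
prepare_structure <- function(x, config) {
  stopifnot(inherits(x, "backbone"))
  keep <- which(x$mask)
  if (length(keep) == 0L) stop("structure has no unmasked residues")
  graph <- if (config$graph_mode == "cgraph") build_cgraph(x, config$cutoff)
           else build_knn(x, config$k)
  graph <- enumerate_soe(graph)
  frames <- local_frames(x)
  nf <- node_features(x, frames)[keep, , drop = FALSE]
  st <- edge_static_blocks(x, graph, frames)
  src_u <- match(graph$src, keep)
  dst_u <- match(graph$dst, keep)
  E <- length(src_u)
  # second-order-edge triples: term t couples edge (s,n), edge (n,t) and
  # edge (s,t); in knn mode triples whose constituent edges are absent are
  # dropped
  L <- x$length
  ekey <- (graph$src - 1) * L + graph$dst
  t_edge <- integer(0); t_in <- integer(0); t_nj <- integer(0)
  if (config$use_soe) {
    ns <- lengths(graph$soe)
    t_edge <- rep(seq_len(E), ns)
    shared <- unlist(graph$soe, use.names = FALSE)
    if (length(shared)) {
      e_in <- match((graph$src[t_edge] - 1) * L + shared, ekey)
      e_nj <- match((shared - 1) * L + graph$dst[t_edge], ekey)
      ok <- !is.na(e_in) & !is.na(e_nj)
      t_edge <- t_edge[ok]; t_in <- e_in[ok]; t_nj <- e_nj[ok]
    }
  }
  soe_count <- tabulate(t_edge, nbins = E)
  u <- (x$ca - x$n)[keep, , drop = FALSE]
  v <- (x$c - x$ca)[keep, , drop = FALSE]
  w3 <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  A5 <- edge_atom_stack(x, virtual_atom_init())[keep, 1:5, , drop = FALSE]
  labels <- if (!is.null(x$native_seq)) seq_to_idx(x$native_seq)[keep] else NULL
  Lu <- length(keep)
  list(keep = keep, n_nodes = Lu, E = E,
       src = src_u, dst = dst_u,
       reverse_index = graph$reverse_index,
       has_reverse = !any(is.na(graph$reverse_index)),
       t_edge = t_edge, t_in = t_in, t_nj = t_nj,
       soe_scale = ifelse(soe_count > 0, 1 / pmax(soe_count, 1L), 0),
       node_feats = nf,
       const_uv = st$uv, const_qp = cbind(st$quat, st$pe),
       u = u, v = v, w = w3, ca = x$ca[keep, , drop = FALSE], A5 = A5,
       labels = labels, L_full = x$length,
       gid = rep(1L, Lu), n_graphs = 1L, gid_split = list(seq_len(Lu)))
}

# Merge several prepared structures into one disjoint-union graph so a
# whole batch runs through a single forward/backward pass.  Per-structure
# operations (global context, attention groups) stay separated through the
# graph-id vector, so batched logits equal the per-structure logits.
prepare_batch <- function(pcs) {
  if (length(pcs) == 1L) return(pcs[[1L]])
  n_off <- cumsum(c(0L, vapply(pcs, function(p) p$n_nodes, integer(1))))
  e_off <- cumsum(c(0L, vapply(pcs, function(p) p$E, integer(1))))
  cat_rows <- function(fld) do.call(rbind, lapply(pcs, function(p) p[[fld]]))
  src <- unlist(lapply(seq_along(pcs), function(i) pcs[[i]]$src + n_off[i]))
  dst <- unlist(lapply(seq_along(pcs), function(i) pcs[[i]]$dst + n_off[i]))
  gid <- unlist(lapply(seq_along(pcs), function(i)
    rep(i, pcs[[i]]$n_nodes)))
  list(n_nodes = n_off[length(n_off)], E = e_off[length(e_off)],
       src = src, dst = dst,
       reverse_index = unlist(lapply(seq_along(pcs), function(i)
         pcs[[i]]$reverse_index + e_off[i])),
       has_reverse = all(vapply(pcs, function(p) p$has_reverse, logical(1))),
       t_edge = unlist(lapply(seq_along(pcs), function(i)
         pcs[[i]]$t_edge + e_off[i])),
       t_in = unlist(lapply(seq_along(pcs), function(i)
         pcs[[i]]$t_in + e_off[i])),
       t_nj = unlist(lapply(seq_along(pcs), function(i)
         pcs[[i]]$t_nj + e_off[i])),
       soe_scale = unlist(lapply(pcs, function(p) p$soe_scale)),
       node_feats = cat_rows("node_feats"),
       const_uv = cat_rows("const_uv"), const_qp = cat_rows("const_qp"),
       u = cat_rows("u"), v = cat_rows("v"), w = cat_rows("w"),
       ca = cat_rows("ca"),
       A5 = {
         A <- array(0, c(n_off[length(n_off)], 5L, 3L))
         for (i in seq_along(pcs))
           A[n_off[i] + seq_len(pcs[[i]]$n_nodes), , ] <- pcs[[i]]$A5
         A
       },
       labels = unlist(lapply(pcs, function(p) p$labels)),
       L_full = NA_integer_,
       gid = gid, n_graphs = length(pcs),
       gid_split = lapply(seq_along(pcs), function(i)
         n_off[i] + seq_len(pcs[[i]]$n_nodes)))
}

# Differentiable edge-distance block: the E x 1024 RBF-encoded interatomic
# distances, with gradient flowing into the raw virtual-atom coefficients
# (through the unit-sphere projection).  Distances among the five fixed
# backbone atoms contribute no parameter gradient.
ad_edge_dist_rbf <- function(tape, va, pc, n_bins = 16L, d_min = 2, d_max = 22) {
  centers <- seq(d_min, d_max, length.out = n_bins)
  sigma <- (d_max - d_min) / (n_bins - 1)
  p <- va$value
  nr <- sqrt(rowSums(p^2))
  phat <- p / nr
  Lu <- pc$n_nodes
  A <- vector("list", 8L)
  for (a in 1:5) A[[a]] <- matrix(pc$A5[, a, ], ncol = 3)
  for (a in 1:3)
    A[[5L + a]] <- pc$ca + phat[a, 1] * pc$u + phat[a, 2] * pc$v +
      phat[a, 3] * pc$w
  E <- pc$E
  R <- matrix(0, E, 1024)
  # cache per-pair distances and offsets of the parameter-dependent pairs
  Dk <- vector("list", 64L)
  diffk <- vector("list", 64L)
  k <- 0L
  for (ai in 1:8) for (aj in 1:8) {
    k <- k + 1L
    diff <- A[[ai]][pc$dst, , drop = FALSE] - A[[aj]][pc$src, , drop = FALSE]
    d <- sqrt(rowSums(diff^2))
    R[, (k - 1L) * n_bins + seq_len(n_bins)] <-
      exp(-(outer(d, centers, `-`) / sigma)^2)
    if (ai > 5L || aj > 5L) { Dk[[k]] <- d; diffk[[k]] <- diff }
  }
  ad_node(tape, R, backward = function(g, nd) {
    dPos <- vector("list", 3L)   # grad wrt the 3 virtual atoms' positions
    for (a in 1:3) dPos[[a]] <- matrix(0, Lu, 3)
    k <- 0L
    for (ai in 1:8) for (aj in 1:8) {
      k <- k + 1L
      if (ai <= 5L && aj <= 5L) next
      cols <- (k - 1L) * n_bins + seq_len(n_bins)
      d <- Dk[[k]]
      # dL/dd_e = sum_k g * rbf * (-2 (d - c_k) / sigma^2)
      dd <- rowSums(g[, cols, drop = FALSE] * R[, cols, drop = FALSE] *
                      (-2 / sigma^2) *
                      outer(d, centers, `-`))
      gvec <- diffk[[k]] * (dd / pmax(d, 1e-12))
      if (ai > 5L) {
        rs <- rowsum(gvec, pc$dst)
        rows <- as.integer(rownames(rs))
        dPos[[ai - 5L]][rows, ] <- dPos[[ai - 5L]][rows, ] + rs
      }
      if (aj > 5L) {
        rs <- rowsum(-gvec, pc$src)
        rows <- as.integer(rownames(rs))
        dPos[[aj - 5L]][rows, ] <- dPos[[aj - 5L]][rows, ] + rs
      }
    }
    dphat <- matrix(0, 3, 3)
    for (a in 1:3)
      dphat[a, ] <- c(sum(dPos[[a]] * pc$u), sum(dPos[[a]] * pc$v),
                      sum(dPos[[a]] * pc$w))
    # through the unit-sphere projection p -> p/||p||
    dp <- (dphat - phat * rowSums(dphat * phat)) / nr
    ad_accum(va, dp)
  })
}

mlp_apply <- function(tape, pn, prefix, x) {
  h <- ad_linear(tape, x, pn[[paste0(prefix, ".W1")]], pn[[paste0(prefix, ".b1")]])
  h <- ad_gelu(tape, h)
  ad_linear(tape, h, pn[[paste0(prefix, ".W2")]], pn[[paste0(prefix, ".b2")]])
}

ln_apply <- function(tape, pn, prefix, x) {
  ad_layernorm(tape, x, pn[[paste0(prefix, ".gamma")]], pn[[paste0(prefix, ".beta")]])
}

sk_apply <- function(tape, pn, prefix, branches) {
  ssum <- Reduce(function(a, b) ad_add(tape, a, b), branches)
  fsq <- mlp_apply(tape, pn, paste0(prefix, ".squeeze"), ssum)
  logits <- lapply(seq_along(branches), function(b)
    mlp_apply(tape, pn, paste0(prefix, ".exc", b), fsq))
  ad_sk_mix(tape, logits, branches)
}

avg_pool <- function(tape, branches) {
  ad_scale(tape, Reduce(function(a, b) ad_add(tape, a, b), branches),
           1 / length(branches))
}

# Core graph forward pass on an existing tape; returns the logits node.
forward_graph <- function(tape, pn, cfg, pc, training = FALSE) {
  drop_p <- if (training) cfg$dropout else 0
  h <- ad_linear(tape, ad_const(tape, pc$node_feats),
                 pn[["node_proj.W"]], pn[["node_proj.b"]])
  h <- ln_apply(tape, pn, "node_proj.ln", h)
  dist_block <- ad_edge_dist_rbf(tape, pn[["va"]], pc)
  e_in <- ad_concat(tape, list(ad_const(tape, pc$const_uv), dist_block,
                               ad_const(tape, pc$const_qp)))
  e <- ad_linear(tape, e_in, pn[["edge_proj.W"]], pn[["edge_proj.b"]])
  e <- ln_apply(tape, pn, "edge_proj.ln", e)
  for (l in seq_len(cfg$n_blocks)) {
    pre <- paste0("blk", l)
    # --- edge update ---
    ehat <- mlp_apply(tape, pn, paste0(pre, ".edge.basic"),
                      ad_concat(tape, list(ad_gather(tape, h, pc$src), e,
                                           ad_gather(tape, h, pc$dst))))
    branches <- list()
    if (cfg$use_symmetric) {
      if (!pc$has_reverse)
        stop("symmetric edge update requires reverse edges; ",
             "set use_symmetric = FALSE for this graph")
      esym <- mlp_apply(tape, pn, paste0(pre, ".edge.sym"),
                        ad_concat(tape, list(ehat,
                                             ad_gather(tape, ehat, pc$reverse_index))))
      branches <- c(branches, list(esym))
    }
    if (cfg$use_soe) {
      if (length(pc$t_edge) > 0) {
        terms <- mlp_apply(tape, pn, paste0(pre, ".edge.soe"),
                           ad_concat(tape, list(ad_gather(tape, ehat, pc$t_in),
                                                ad_gather(tape, ehat, pc$t_nj),
                                                ad_gather(tape, ehat, pc$t_edge))))
        esoe <- ad_rowscale_const(tape,
                                  ad_scatter_sum(tape, terms, pc$t_edge, pc$E),
                                  pc$soe_scale)
      } else {
        esoe <- ad_const(tape, matrix(0, pc$E, cfg$hidden))
      }
      branches <- c(branches, list(esoe))
    }
    e2 <- mlp_apply(tape, pn, paste0(pre, ".edge.e2"), ehat)
    branches <- c(branches, list(e2))
    egraph <- if (cfg$use_sk_edges)
      sk_apply(tape, pn, paste0(pre, ".edge.sk"), branches)
    else avg_pool(tape, branches)
    e <- ln_apply(tape, pn, paste0(pre, ".edge.ln1"),
                  ad_add(tape, e, ad_dropout(tape, egraph, drop_p)))
    ffn <- mlp_apply(tape, pn, paste0(pre, ".edge.ffn"), e)
    e <- ln_apply(tape, pn, paste0(pre, ".edge.ln2"),
                  ad_add(tape, e, ad_dropout(tape, ffn, drop_p)))
    # --- node update ---
    q <- mlp_apply(tape, pn, paste0(pre, ".node.q"), h)
    k <- mlp_apply(tape, pn, paste0(pre, ".node.k"), e)
    score <- ad_rowsum(tape, ad_mul(tape, ad_gather(tape, q, pc$dst), k))
    if (cfg$attention_scale)
      score <- ad_scale(tape, score, 1 / sqrt(cfg$hidden))
    a <- ad_segment_softmax(tape, score, pc$dst)
    vfeat <- mlp_apply(tape, pn, paste0(pre, ".node.v"),
                       ad_concat(tape, list(ad_gather(tape, h, pc$src), e,
                                            ad_gather(tape, h, pc$dst))))
    hlocal <- ad_scatter_sum(tape, ad_rowscale(tape, vfeat, a),
                             pc$dst, pc$n_nodes)
    ga <- ad_group_col_softmax(tape,
                               mlp_apply(tape, pn, paste0(pre, ".node.ga"), h),
                               pc$gid, pc$gid_split, pc$n_graphs)
    gv <- mlp_apply(tape, pn, paste0(pre, ".node.gv"), h)
    G <- ad_group_colsum(tape, ad_mul(tape, ga, gv), pc$gid, pc$n_graphs)
    hglobal <- mlp_apply(tape, pn, paste0(pre, ".node.gout"),
                         ad_concat(tape, list(h, ad_gather(tape, G, pc$gid))))
    hgraph <- if (cfg$use_sk_nodes)
      sk_apply(tape, pn, paste0(pre, ".node.sk"), list(hlocal, hglobal))
    else avg_pool(tape, list(hlocal, hglobal))
    # the first node residual deliberately carries no dropout,
    # unlike the edge residual
    h <- ln_apply(tape, pn, paste0(pre, ".node.ln1"), ad_add(tape, h, hgraph))
    ffn <- mlp_apply(tape, pn, paste0(pre, ".node.ffn"), h)
    h <- ln_apply(tape, pn, paste0(pre, ".node.ln2"),
                  ad_add(tape, h, ad_dropout(tape, ffn, drop_p)))
  }
  ad_linear(tape, h, pn[["head.W"]], pn[["head.b"]])
}

make_param_nodes <- function(tape, model) {
  pn <- list()
  for (nm in names(model$params)) {
    val <- model$params[[nm]]
    pn[[nm]] <- ad_param(tape, if (is.matrix(val)) val else val)
  }
  pn
}

#' Forward pass
#'
#' Runs the network on one backbone and returns per-residue 20-class
#' logits.  Masked residues are excluded from the graph and the features;
#' their logit rows are `NA` sentinels.  With dropout disabled (the
#' default) the forward pass is deterministic.
#'
#' @param model a `cgnn_model`.
#' @param x a [backbone], or a precomputed structure from the internal
#'   preparation step.
#' @return L x 20 matrix of logits.
#' @export
cgnn_forward <- function(model, x) {
  stopifnot(inherits(model, "cgnn_model"))
  pc <- if (inherits(x, "backbone")) prepare_structure(x, model$config) else x
  tape <- ad_tape()
  pn <- make_param_nodes(tape, model)
  logits <- forward_graph(tape, pn, model$config, pc, training = FALSE)
  L <- pc$L_full
  out <- matrix(NA_real_, L, model$config$n_classes)
  out[pc$keep, ] <- logits$value
  out
}

#' Design probabilities
#'
#' Softmax of the forward logits: the per-residue categorical design
#' distribution over the 20 amino acids (rows of masked residues are `NA`).
#'
#' @inheritParams cgnn_forward
#' @return L x 20 matrix of probabilities.
#' @export
cgnn_probs <- function(model, x) {
  logits <- cgnn_forward(model, x)
  t(apply(logits, 1, function(r) {
    if (any(is.na(r))) return(rep(NA_real_, length(r)))
    e <- exp(r - max(r)); e / sum(e)
  }))
}

#' Save / load model checkpoints
#'
#' Checkpoints are single JSON files carrying a format version, the full
#' configuration echo, the seed, and all parameter arrays, so any result
#' can be regenerated exactly.
#'
#' @param model a `cgnn_model`.
#' @param path checkpoint path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `cgnn_model`.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    format = "cgraphdesign-checkpoint-1",
    config = unclass(model$config),
    seed = model$seed,
    params = lapply(model$params, function(p)
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "cgraphdesign-checkpoint-1"))
    stop("unrecognized checkpoint format in ", path)
  cfg <- payload$config
  config <- cgnn_config(hidden = cfg$hidden, n_blocks = cfg$n_blocks,
                        dropout = cfg$dropout,
                        use_symmetric = cfg$use_symmetric,
                        use_soe = cfg$use_soe,
                        use_sk_edges = cfg$use_sk_edges,
                        use_sk_nodes = cfg$use_sk_nodes,
                        graph_mode = cfg$graph_mode, cutoff = cfg$cutoff,
                        k = cfg$k, attention_scale = cfg$attention_scale,
                        n_classes = cfg$n_classes)
  params <- lapply(payload$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2)
      matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  structure(list(config = config, params = params,
                 seed = as.integer(payload$seed)),
            class = "cgnn_model")
}
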