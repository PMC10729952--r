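#' Virtual C-beta coordinates
#'
#' Computes the pseudo side-chain atom used for contact definition, for all
#' residues including glycine:
#' `r_Cb = -0.58273431 u + 0.56802827 v - 0.54067466 (u x v) + r_Ca`
#' with `u = r_Ca - r_N` and `v = r_C - r_Ca`.  Masked residues yield `NA`
#' rows.
#'
#' @param x a [backbone].
#' @return L x 3 matrix of Angstrom coordinates.
#' @export
virtual_cbeta <- function(x) {
  stopifnot(inherits(x, "backbone"))
  u <- x$ca - x$n
  v <- x$c - x$ca
  w <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  cb <- -0.58273431 * u + 0.56802827 * v - 0.54067466 * w + x$ca
  cb[!x$mask, ] <- NA_real_
  cb
}

new_contact_graph <- function(mode, src, dst, dist, n_nodes, mask,
                              cutoff = NA_real_, k = NA_integer_) {
  E <- length(src)
  # reverse_index: edge (i,j) -> index of (j,i) where it exists
  fwd <- src * (n_nodes + 1) + dst
  rev <- dst * (n_nodes + 1) + src
  reverse_index <- match(rev, fwd)
  neighbors <- vector("list", n_nodes)
  if (E > 0) {
    by_dst <- split(src, factor(dst, levels = seq_len(n_nodes)))
    neighbors <- lapply(by_dst, function(v) sort(unique(v)))
  }
  structure(list(mode = mode, cutoff = cutoff, k = k,
                 n_nodes = n_nodes, mask = mask,
                 src = src, dst = dst, dist = dist,
                 reverse_index = reverse_index,
                 neighbors = neighbors,
                 soe = NULL),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("<contact_graph> %s (%s), %d nodes, %d directed edges\n",
              x$mode,
              if (x$mode == "cgraph") paste0(x$cutoff, " A cutoff")
              else paste0("k=", x$k),
              x$n_nodes, length(x$src)))
  invisible(x)
}

#' Build a contact-map graph
#'
#' Connects every unmasked residue pair whose virtual C-beta distance is at
#' most `cutoff` (boundary inclusive) with a pair of directed edges; no
#' self-loops.  Edges are stored as (src = j, dst = i) pairs: the edge
#' carries information from residue j to residue i.  `reverse_index` maps
#' every edge to its symmetric partner and is an involution.
#'
#' @param x a [backbone].
#' @param cutoff contact cutoff in Angstrom (> 0); default 12.
#' @return A `contact_graph` object.
#' @export
build_cgraph <- function(x, cutoff = 12) {
  stopifnot(inherits(x, "backbone"))
  if (cutoff <= 0) stop("cutoff must be positive")
  if (!any(x$mask)) stop("no unmasked residues")
  cb <- virtual_cbeta(x)
  L <- x$length
  d <- as.matrix(stats::dist(cb))
  d[is.na(d)] <- Inf
  diag(d) <- Inf
  hit <- which(d <= cutoff, arr.ind = TRUE)
  ord <- order(hit[, "col"], hit[, "row"])   # group edges by target residue
  src <- unname(hit[ord, "row"])
  dst <- unname(hit[ord, "col"])
  new_contact_graph("cgraph", src, dst, d[cbind(src, dst)],
                    n_nodes = L, mask = x$mask, cutoff = cutoff)
}

#' Build a k-nearest-neighbor graph
#'
#' Each unmasked residue receives edges from its `k` nearest unmasked
#' residues by virtual C-beta distance (fewer when fewer exist).  Distance
#' ties are broken by the lower residue index so construction is
#' deterministic.  The graph may be asymmetric; `reverse_index` is `NA`
#' where no reverse edge exists.
#'
#' @param x a [backbone].
#' @param k neighbor count (> 0); default 30.
#' @return A `contact_graph` object.
#' @export
build_knn <- function(x, k = 30) {
  stopifnot(inherits(x, "backbone"))
  if (k <= 0) stop("k must be positive")
  if (!any(x$mask)) stop("no unmasked residues")
  cb <- virtual_cbeta(x)
  L <- x$length
  d <- as.matrix(stats::dist(cb))
  d[is.na(d)] <- Inf
  diag(d) <- Inf
  src <- integer(0); dst <- integer(0)
  for (i in which(x$mask)) {
    ord <- order(d[, i], seq_len(L))       # ties -> lower residue index
    nb <- ord[is.finite(d[ord, i])]
    nb <- nb[seq_len(min(k, length(nb)))]
    src <- c(src, sort(nb))
    dst <- c(dst, rep(i, length(nb)))
  }
  new_contact_graph("knn", src, dst, d[cbind(src, dst)],
                    n_nodes = L, mask = x$mask, k = as.integer(k))
}

#' Enumerate second-order edges
#'
#' For every directed edge (j -> i) records the sorted list of shared
#' neighbors `n` in the intersection of the neighbor sets of i and j.
#' Second-order edges enrich edge updates by composing the edges (i,n) and
#' (n,j) through each shared neighbor.
#'
#' @param graph a `contact_graph`.
#' @return The graph with its `soe` field filled: a list (one entry per
#'   edge) of integer vectors, possibly empty.
#' @export
enumerate_soe <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  nb <- graph$neighbors
  E <- length(graph$src)
  soe <- vector("list", E)
  for (e in seq_len(E)) {
    i <- graph$dst[e]; j <- graph$src[e]
    soe[[e]] <- sort(intersect(nb[[i]], nb[[j]]))
  }
  graph$soe <- soe
  graph
}

#' Serialize a graph to a TSV edge list
#'
#' Debug output: one row per directed edge with source, target and virtual
#' C-beta distance.
#'
#' @param graph a `contact_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "contact_graph"))
  utils::write.table(
    data.frame(source = graph$src, target = graph$dst,
               distance = round(graph$dist, 4)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
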