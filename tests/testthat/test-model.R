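small_model <- function(seed = 1L, ...) {
  cgnn_init(cgnn_config(hidden = 16L, n_blocks = 1L, ...), seed = seed)
}

test_that("selective kernel weights sum to one per dimension and pass single branches through", {
  ad <- asNamespace("cgraphdesign")
  set.seed(41)
  tape <- ad$ad_tape()
  logits <- lapply(1:3, function(i) ad$ad_const(tape, matrix(rnorm(12), 4, 3)))
  branches <- lapply(1:3, function(i) ad$ad_const(tape, matrix(rnorm(12), 4, 3)))
  merged <- ad$ad_sk_mix(tape, logits, branches)
  # recompute weights and check normalization
  mx <- Reduce(pmax, lapply(logits, function(l) l$value))
  ev <- lapply(logits, function(l) exp(l$value - mx))
  den <- Reduce(`+`, ev)
  wsum <- Reduce(`+`, lapply(ev, function(e) e / den))
  expect_equal(wsum, matrix(1, 4, 3), tolerance = 1e-6)
  # single branch: softmax of one logit is 1 everywhere
  t2 <- ad$ad_tape()
  one <- ad$ad_const(t2, matrix(rnorm(12), 4, 3))
  lone <- ad$ad_const(t2, matrix(rnorm(12), 4, 3))
  expect_equal(ad$ad_sk_mix(t2, list(lone), list(one))$value, one$value)
  # equal excitation logits -> arithmetic mean of branches
  t3 <- ad$ad_tape()
  lg <- matrix(rnorm(12), 4, 3)
  same <- lapply(1:3, function(i) ad$ad_const(t3, lg))
  mean_out <- ad$ad_sk_mix(t3, same, branches_marked <- lapply(branches, function(b) ad$ad_const(t3, b$value)))
  expect_equal(mean_out$value,
               Reduce(`+`, lapply(branches, function(b) b$value)) / 3,
               tolerance = 1e-12)
})

test_that("attention weights over in-neighbors sum to one per node", {
  bb <- fixture_backbone(seed = 42L)
  cfg <- cgnn_config(hidden = 16L, n_blocks = 1L)
  pc <- cgraphdesign:::prepare_structure(bb, cfg)
  ad <- asNamespace("cgraphdesign")
  tape <- ad$ad_tape()
  scores <- ad$ad_const(tape, matrix(rnorm(pc$E), ncol = 1))
  a <- ad$ad_segment_softmax(tape, scores, pc$dst)
  sums <- as.numeric(tapply(a$value[, 1], pc$dst, sum))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-6)
})

test_that("global context weights sum to one per dimension and are permutation-invariant", {
  ad <- asNamespace("cgraphdesign")
  set.seed(43)
  x <- matrix(rnorm(30), 10, 3)
  tape <- ad$ad_tape()
  p <- ad$ad_group_col_softmax(tape, ad$ad_const(tape, x),
                               rep(1L, 10), list(1:10), 1L)
  expect_equal(colSums(p$value), rep(1, 3), tolerance = 1e-6)
  G <- colSums(p$value * x)
  perm <- sample(10)
  t2 <- ad$ad_tape()
  p2 <- ad$ad_group_col_softmax(t2, ad$ad_const(t2, x[perm, ]),
                                rep(1L, 10), list(1:10), 1L)
  expect_equal(colSums(p2$value * x[perm, ]), G, tolerance = 1e-6)
})

test_that("second-order-edge model update equals triple-loop brute force", {
  bb <- fixture_backbone(seed = 44L)
  cfg <- cgnn_config(hidden = 8L, n_blocks = 1L)
  model <- cgnn_init(cfg, seed = 3L)
  pc <- cgraphdesign:::prepare_structure(bb, cfg)
  ad <- asNamespace("cgraphdesign")
  set.seed(5)
  ehat_val <- matrix(rnorm(pc$E * 8), pc$E, 8)
  tape <- ad$ad_tape()
  pn <- cgraphdesign:::make_param_nodes(tape, model)
  ehat <- ad$ad_const(tape, ehat_val)
  terms <- cgraphdesign:::mlp_apply(tape, pn, "blk1.edge.soe",
    ad$ad_concat(tape, list(ad$ad_gather(tape, ehat, pc$t_in),
                            ad$ad_gather(tape, ehat, pc$t_nj),
                            ad$ad_gather(tape, ehat, pc$t_edge))))
  esoe <- ad$ad_rowscale_const(tape,
    ad$ad_scatter_sum(tape, terms, pc$t_edge, pc$E), pc$soe_scale)
  # brute force: explicit mean over shared neighbors per edge
  mlp_ref <- function(x) {
    h <- x %*% model$params[["blk1.edge.soe.W1"]]
    h <- sweep(h, 2, model$params[["blk1.edge.soe.b1"]], "+")
    s <- 1 / (1 + exp(-1.702 * h)); h <- h * s
    sweep(h %*% model$params[["blk1.edge.soe.W2"]], 2,
          model$params[["blk1.edge.soe.b2"]], "+")
  }
  graph <- enumerate_soe(build_cgraph(bb, cfg$cutoff))
  L <- bb$length
  ekey <- paste(graph$src, graph$dst)
  for (e in sample(pc$E, 10)) {
    shared <- graph$soe[[e]]
    if (length(shared) == 0) {
      expect_equal(esoe$value[e, ], rep(0, 8))
      next
    }
    acc <- matrix(0, 1, 8)
    for (n in shared) {
      e_in <- match(paste(graph$src[e], n), ekey)
      e_nj <- match(paste(n, graph$dst[e]), ekey)
      acc <- acc + mlp_ref(cbind(ehat_val[e_in, , drop = FALSE],
                                 ehat_val[e_nj, , drop = FALSE],
                                 ehat_val[e, , drop = FALSE]))
    }
    expect_equal(esoe$value[e, ], as.numeric(acc / length(shared)),
                 tolerance = 1e-5)
  }
})

test_that("forward logits are finite, shaped L x 20, and deterministic", {
  bb <- fixture_backbone(seed = 45L)
  model <- small_model(seed = 2L)
  lg <- cgnn_forward(model, bb)
  expect_equal(dim(lg), c(bb$length, 20L))
  expect_true(all(is.finite(lg)))
  expect_identical(cgnn_forward(model, bb), lg)
})

test_that("end-to-end logits are rigid-motion invariant", {
  bb <- fixture_backbone(seed = 46L)
  model <- cgnn_init(cgnn_config(hidden = 32L, n_blocks = 3L), seed = 5L)
  lg <- cgnn_forward(model, bb)
  set.seed(99)
  worst <- 0
  for (r in 1:5) {
    moved <- transform_backbone(bb, random_rotation(),
                                stats::rnorm(3, sd = 30))
    worst <- max(worst, max(abs(cgnn_forward(model, moved) - lg)))
  }
  expect_lt(worst, 1e-3)
})

test_that("masked residues emit sentinel rows and are excluded from the graph", {
  bb <- fixture_backbone(seed = 47L)
  bb$mask[7] <- FALSE
  model <- small_model(seed = 2L)
  lg <- cgnn_forward(model, bb)
  expect_true(all(is.na(lg[7, ])))
  expect_true(all(is.finite(lg[-7, ])))
})

test_that("renumbering that preserves offsets leaves logits unchanged", {
  bb <- fixture_backbone(seed = 48L)
  model <- small_model(seed = 6L)
  bb2 <- bb
  bb2$residue_ids <- as.character(1000L + seq_len(bb$length))
  expect_identical(cgnn_forward(model, bb2), cgnn_forward(model, bb))
})

test_that("batched forward gives identical logits to separate processing", {
  ds <- learnability_dataset(3, 24, seed = 500)
  cfg <- cgnn_config(hidden = 16L, n_blocks = 2L)
  model <- cgnn_init(cfg, seed = 7L)
  pcs <- lapply(ds, cgraphdesign:::prepare_structure, config = cfg)
  pcb <- cgraphdesign:::prepare_batch(pcs)
  ad <- asNamespace("cgraphdesign")
  tape <- ad$ad_tape()
  pn <- cgraphdesign:::make_param_nodes(tape, model)
  joint <- cgraphdesign:::forward_graph(tape, pn, cfg, pcb, training = FALSE)$value
  off <- 0L
  for (i in seq_along(ds)) {
    lg <- cgnn_forward(model, ds[[i]])
    expect_lt(max(abs(lg - joint[off + seq_len(nrow(lg)), ])), 1e-12)
    off <- off + nrow(lg)
  }
})

test_that("ablation variants change wiring, parameter count and outputs", {
  bb <- fixture_backbone(seed = 49L)
  variants <- c("full", "model1", "model3", "model4")
  models <- lapply(variants, function(v)
    cgnn_init(ablation_config(v, hidden = 16L, n_blocks = 1L), seed = 9L))
  names(models) <- variants
  counts <- vapply(models, count_params, numeric(1))
  expect_true(length(unique(counts)) == length(counts) - 0L ||
                all(counts[c("model1", "model3")] != counts["full"]))
  expect_lt(counts["model1"], counts["model3"])   # no SOE MLP or third SK branch
  expect_lt(counts["model4"], counts["full"])     # no SK parameters at all
  logits <- lapply(models, cgnn_forward, x = bb)
  for (v in c("model1", "model3", "model4"))
    expect_gt(max(abs(logits[[v]] - logits[["full"]])), 1e-6)
  # knn mode refuses symmetric updates with actionable advice
  expect_error(cgnn_config(graph_mode = "knn"), "use_symmetric")
  knn_model <- cgnn_init(cgnn_config(hidden = 16L, n_blocks = 1L,
                                     graph_mode = "knn", k = 10L,
                                     use_symmetric = FALSE), seed = 1L)
  expect_true(all(is.finite(cgnn_forward(knn_model, bb))))
})

test_that("full network analytic gradients match central differences", {
  bb <- make_backbone(synthetic_spec(
    data.frame(type = c("helix", "coil"), length = c(5, 5)), seed = 2L))
  bb$native_seq <- label_sequence(bb)
  cfg <- cgnn_config(hidden = 8L, n_blocks = 1L)
  model <- cgnn_init(cfg, seed = 4L)
  pc <- cgraphdesign:::prepare_structure(bb, cfg)
  loss_of <- function(m) {
    tape <- cgraphdesign:::ad_tape()
    pn <- cgraphdesign:::make_param_nodes(tape, m)
    lg <- cgraphdesign:::forward_graph(tape, pn, cfg, pc)
    cgraphdesign:::ad_ce_loss(tape, lg, pc$labels)$value[1]
  }
  tape <- cgraphdesign:::ad_tape()
  pn <- cgraphdesign:::make_param_nodes(tape, model)
  lg <- cgraphdesign:::forward_graph(tape, pn, cfg, pc)
  loss <- cgraphdesign:::ad_ce_loss(tape, lg, pc$labels)
  cgraphdesign:::ad_backward(tape, loss)
  set.seed(10)
  checked <- c(sample(names(model$params), 8), "va")
  for (nm in checked) {
    k <- sample(length(model$params[[nm]]), 1)
    eps <- 1e-5
    mp <- model; mp$params[[nm]][k] <- mp$params[[nm]][k] + eps
    mm <- model; mm$params[[nm]][k] <- mm$params[[nm]][k] - eps
    num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
    expect_equal(pn[[nm]]$grad[k], num, tolerance = 1e-4,
                 label = paste("grad of", nm))
  }
})

test_that("checkpoints round-trip through JSON exactly enough to reproduce logits", {
  bb <- fixture_backbone(seed = 51L)
  model <- small_model(seed = 11L)
  path <- tempfile(fileext = ".json")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_equal(back$config, model$config)
  expect_equal(cgnn_forward(back, bb), cgnn_forward(model, bb),
               tolerance = 1e-12)
  expect_error(suppressWarnings(load_checkpoint(tempfile())),
               "cannot open|No such|not")
})

test_that("describe reports a parameter table consistent with count_params", {
  model <- small_model(seed = 1L)
  txt <- utils::capture.output(tab <- describe_model(model))
  expect_true(any(grepl("total parameters", txt)))
  expect_equal(sum(tab$count), count_params(model))
})
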