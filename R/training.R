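#' Training configuration
#'
#' Desk-scale training recipe: cross-entropy loss, AdamW, OneCycle learning
#' rate schedule peaking at `max_lr`, residue-budget batching, optional
#' Gaussian coordinate-noise augmentation.
#'
#' @param epochs training epochs (default 100).
#' @param max_lr OneCycle peak learning rate (default 0.004).
#' @param batch_residues maximum residues per batch (default 4096).
#' @param noise_sd coordinate-noise augmentation sd in Angstrom (default 0;
#'   0.02 enables the augmentation studied for generated structures).
#' @param weight_decay AdamW decoupled weight decay (default 0.01).
#' @param beta1,beta2,eps AdamW moment constants (common defaults).
#' @param pct_start OneCycle warm-up fraction (default 0.3).
#' @param div_factor initial lr = max_lr / div_factor (default 25).
#' @param final_div_factor final lr = max_lr / final_div_factor
#'   (default 1e4).
#' @param grad_clip optional global gradient-norm clip (`Inf` = off).
#' @param seed integer seed controlling batching, dropout and augmentation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, max_lr = 0.004,
                         batch_residues = 4096L, noise_sd = 0,
                         weight_decay = 0.01, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, pct_start = 0.3, div_factor = 25,
                         final_div_factor = 1e4, grad_clip = Inf,
                         seed = 1L) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (noise_sd < 0) stop("noise sd must be >= 0")
  structure(list(epochs = as.integer(epochs), max_lr = max_lr,
                 batch_residues = as.integer(batch_residues),
                 noise_sd = noise_sd, weight_decay = weight_decay,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 pct_start = pct_start, div_factor = div_factor,
                 final_div_factor = final_div_factor, grad_clip = grad_clip,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Sequence cross-entropy loss
#'
#' Mean categorical cross-entropy (natural log, no label smoothing) of the
#' native residues under the predicted logits, over unmasked positions.
#'
#' @param logits L x 20 matrix of logits (masked rows may be `NA`).
#' @param native_seq native sequence string of length L.
#' @param mask logical vector; positions counted in the loss.  Defaults to
#'   rows with finite logits and known residues.
#' @return Scalar loss (natural log units).
#' @export
sequence_loss <- function(logits, native_seq, mask = NULL) {
  idx <- seq_to_idx(native_seq)
  ok <- !is.na(idx) & apply(is.finite(logits), 1, all)
  if (!is.null(mask)) ok <- ok & mask
  if (!any(ok)) stop("loss undefined: no unmasked residues with labels")
  lv <- logits[ok, , drop = FALSE]
  mx <- apply(lv, 1, max)
  lse <- mx + log(rowSums(exp(lv - mx)))
  mean(lse - lv[cbind(seq_len(nrow(lv)), idx[ok])])
}

#' Residue-budget batching
#'
#' Randomly permutes the dataset each epoch (seeded) and packs structures
#' greedily so that no batch exceeds `budget` residues; every structure
#' appears exactly once per epoch.
#'
#' @param lengths integer vector of structure lengths.
#' @param budget maximum residues per batch.
#' @param seed integer seed.
#' @return List of integer index vectors, one per batch.
#' @export
make_batches <- function(lengths, budget = 4096L, seed = 1L) {
  if (any(lengths > budget))
    stop("structure of ", max(lengths), " residues exceeds the batch budget ",
         budget, "; increase batch_residues")
  set.seed(seed)
  perm <- sample(length(lengths))
  batches <- list()
  cur <- integer(0); used <- 0L
  for (i in perm) {
    if (used + lengths[i] > budget && length(cur) > 0L) {
      batches[[length(batches) + 1L]] <- cur
      cur <- integer(0); used <- 0L
    }
    cur <- c(cur, i); used <- used + lengths[i]
  }
  if (length(cur) > 0L) batches[[length(batches) + 1L]] <- cur
  batches
}

#' OneCycle learning rate
#'
#' Cosine-annealed OneCycle schedule: warm-up from `max_lr / div_factor` to
#' exactly `max_lr` over the first `pct_start` fraction of steps, then
#' annealing to `max_lr / final_div_factor`.
#'
#' @param step step index (1-based).
#' @param total total number of steps.
#' @param max_lr peak learning rate.
#' @param pct_start warm-up fraction.
#' @param div_factor,final_div_factor initial/final divisors.
#' @return Learning rate at `step`.
#' @export
onecycle_lr <- function(step, total, max_lr = 0.004, pct_start = 0.3,
                        div_factor = 25, final_div_factor = 1e4) {
  s_peak <- max(1L, round(pct_start * total))
  lr0 <- max_lr / div_factor
  lr_end <- max_lr / final_div_factor
  ifelse(step <= s_peak,
         if (s_peak == 1L) max_lr
         else lr0 + (max_lr - lr0) *
           (1 - cos(pi * (step - 1) / (s_peak - 1))) / 2,
         lr_end + (max_lr - lr_end) *
           (1 + cos(pi * (step - s_peak) / max(1L, total - s_peak))) / 2)
}

clone_zero <- function(params) lapply(params, function(p) p * 0)

#' Train a model
#'
#' Full-batch-free training loop at desk scale: per epoch, the dataset is
#' randomly packed into residue-budget batches; for each batch the graph
#' forward/backward pass runs through the shared autodiff tape and one
#' AdamW step is taken at the OneCycle learning rate.  Per-epoch loss and
#' token accuracy are logged as structured records.
#'
#' @param model a `cgnn_model` (updated parameters are returned, the input
#'   is not modified in place).
#' @param dataset list of [backbone] objects with `native_seq` set.
#' @param config a [train_config()].
#' @param verbose print a log line every `verbose` epochs (0 = silent).
#' @return List with `model` (trained), `history` (data frame: epoch, loss,
#'   accuracy, lr), and `config` echo.
#' @export
train_cgnn <- function(model, dataset, config = train_config(), verbose = 0L) {
  stopifnot(inherits(model, "cgnn_model"), inherits(config, "train_config"))
  lens <- vapply(dataset, function(s) sum(s$mask), integer(1))
  for (s in dataset)
    if (is.null(s$native_seq)) stop("every structure needs a native sequence")
  # batch compositions for all epochs are fixed upfront so the OneCycle
  # schedule knows its total step count
  epoch_batches <- lapply(seq_len(config$epochs), function(ep)
    make_batches(lens, config$batch_residues, seed = config$seed + ep))
  total_steps <- sum(lengths(epoch_batches))
  static_pc <- NULL
  if (config$noise_sd == 0)
    static_pc <- lapply(dataset, prepare_structure, config = model$config)
  m_state <- clone_zero(model$params)
  v_state <- clone_zero(model$params)
  step <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0), lr = numeric(0))
  for (ep in seq_len(config$epochs)) {
    if (config$noise_sd > 0) {
      noisy <- lapply(seq_along(dataset), function(i)
        perturb_backbone(dataset[[i]], config$noise_sd,
                         seed = config$seed + 7919L * ep + i))
      pcs <- lapply(noisy, prepare_structure, config = model$config)
    } else pcs <- static_pc
    set.seed(config$seed + 104729L + ep)   # dropout stream for this epoch
    ep_loss_num <- 0; ep_n <- 0L; ep_correct <- 0L
    lr <- NA_real_
    for (batch in epoch_batches[[ep]]) {
      step <- step + 1L
      lr <- onecycle_lr(step, total_steps, config$max_lr, config$pct_start,
                        config$div_factor, config$final_div_factor)
      tape <- ad_tape()
      pn <- make_param_nodes(tape, model)
      # one disjoint-union pass over the whole batch: the pooled mean
      # cross-entropy equals the residue-weighted mean over structures
      pc <- prepare_batch(pcs[batch])
      lab_ok <- !is.na(pc$labels)
      if (!any(lab_ok)) next
      logits <- forward_graph(tape, pn, model$config, pc, training = TRUE)
      use <- if (all(lab_ok)) logits else ad_gather(tape, logits, which(lab_ok))
      loss_node <- ad_ce_loss(tape, use, pc$labels[lab_ok])
      pred <- max.col(logits$value, ties.method = "first")
      ep_correct <- ep_correct + sum(pred[lab_ok] == pc$labels[lab_ok])
      ep_n <- ep_n + sum(lab_ok)
      ep_loss_num <- ep_loss_num + loss_node$value[1] * sum(lab_ok)
      if (!is.finite(loss_node$value[1]))
        stop(sprintf("non-finite loss at epoch %d step %d (lr %.2e)",
                     ep, step, lr))
      ad_backward(tape, loss_node)
      # AdamW update with optional global-norm clipping
      grads <- lapply(pn, function(nd)
        if (is.null(nd$grad)) nd$value * 0 else nd$grad)
      if (is.finite(config$grad_clip)) {
        gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
        if (gn > config$grad_clip)
          grads <- lapply(grads, function(g) g * (config$grad_clip / gn))
      }
      b1 <- config$beta1; b2 <- config$beta2
      bc1 <- 1 - b1^step; bc2 <- 1 - b2^step
      for (nm in names(model$params)) {
        g <- grads[[nm]]
        m_state[[nm]] <- b1 * m_state[[nm]] + (1 - b1) * g
        v_state[[nm]] <- b2 * v_state[[nm]] + (1 - b2) * g^2
        upd <- (m_state[[nm]] / bc1) / (sqrt(v_state[[nm]] / bc2) + config$eps)
        model$params[[nm]] <- model$params[[nm]] -
          lr * (upd + config$weight_decay * model$params[[nm]])
      }
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loss = ep_loss_num / ep_n,
                                accuracy = ep_correct / ep_n, lr = lr))
    if (verbose > 0 && ep %% verbose == 0)
      cat(sprintf("epoch %4d  loss %.4f  acc %.3f  lr %.2e\n",
                  ep, ep_loss_num / ep_n, ep_correct / ep_n, lr))
  }
  list(model = model, history = history, config = config)
}

#' Training-set recovery
#'
#' Convenience: argmax design on every structure and the percentage of
#' residues recovered, pooled over the dataset.
#'
#' @param model a `cgnn_model`.
#' @param dataset list of backbones with native sequences.
#' @return Pooled recovery percentage.
#' @export
dataset_recovery <- function(model, dataset) {
  correct <- 0L; total <- 0L
  for (s in dataset) {
    logits <- cgnn_forward(model, s)
    idx <- seq_to_idx(s$native_seq)
    ok <- !is.na(idx) & apply(is.finite(logits), 1, all)
    pred <- max.col(replace(logits, is.na(logits), -Inf), ties.method = "first")
    correct <- correct + sum(pred[ok] == idx[ok])
    total <- total + sum(ok)
  }
  100 * correct / total
}
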