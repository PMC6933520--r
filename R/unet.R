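#' 3D U-Net architecture configuration
#'
#' Encoder-decoder fully convolutional network with skip connections.
#' Each level holds one block of two nodes, a node being a zero-padded
#' 3x3x3 convolution (stride 1), ReLU and batch normalization.  Levels are
#' joined by 2x2x2 max-pooling on the way down and 2x2x2 transposed
#' convolution on the way up; encoder outputs are concatenated onto the
#' matching decoder inputs.  A final 1x1x1 convolution maps to per-class
#' scores.
#'
#' @param in_channels Input channels (4: T1, T1PC, T2, FLAIR).
#' @param n_classes 4 (background, NCR, ED, AT) or 5 (adding WMH).
#' @param levels Encoding/decoding levels (default 4).
#' @param base_filters Filters at the outermost level (default 32),
#'   doubling at each deeper level.
#' @return Object of class `unet_config`.
#' @export
unet_config <- function(in_channels = 4L, n_classes = 5L, levels = 4L,
                        base_filters = 32L) {
  stopifnot(in_channels >= 1, n_classes %in% c(4L, 5L), levels >= 1,
            base_filters >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 levels = as.integer(levels),
                 base_filters = as.integer(base_filters)),
            class = "unet_config")
}

#' Per-level filter counts
#'
#' @param cfg A [unet_config()].
#' @return Integer vector of length `levels`; element `l` is
#'   `base_filters * 2^(l-1)`.
#' @examples
#' channel_plan(unet_config(levels = 4, base_filters = 32)) # 32 64 128 256
#' @export
channel_plan <- function(cfg) {
  cfg$base_filters * 2L^(seq_len(cfg$levels) - 1L)
}

#' Training configuration
#'
#' @param initial_lr Initial Adam learning rate (default 1e-4).
#' @param epochs Training epochs (default 600).
#' @param lr_decay_power Polynomial decay order (default 2): the rate at
#'   epoch `e` is `initial_lr * (1 - e/epochs)^lr_decay_power`.
#' @param folds Cross-validation folds (default 10).
#' @param ensemble_size Independently retrained members whose softmax
#'   probabilities are averaged at inference (default 10).
#' @param batch_size Patches per optimization step (default 2).
#' @param patches_per_epoch Patches drawn per epoch (default 200).
#' @param loss Only `"cross_entropy"` (unweighted voxelwise multi-class
#'   cross-entropy) is implemented.
#' @param seed Integer seed controlling initialization, sampling and
#'   augmentation.
#' @return Object of class `train_config`.
#' @export
train_config <- function(initial_lr = 1e-4, epochs = 600L,
                         lr_decay_power = 2L, folds = 10L,
                         ensemble_size = 10L, batch_size = 2L,
                         patches_per_epoch = 200L,
                         loss = "cross_entropy", seed = 1L) {
  stopifnot(initial_lr > 0, epochs >= 1, folds >= 2, ensemble_size >= 1,
            batch_size >= 1, patches_per_epoch >= 1,
            loss == "cross_entropy")
  structure(list(initial_lr = initial_lr, epochs = as.integer(epochs),
                 lr_decay_power = as.integer(lr_decay_power),
                 folds = as.integer(folds),
                 ensemble_size = as.integer(ensemble_size),
                 batch_size = as.integer(batch_size),
                 patches_per_epoch = as.integer(patches_per_epoch),
                 loss = loss, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate under 2nd-order polynomial decay
#'
#' @param e Epoch, `0 <= e <= epochs`.
#' @param cfg A [train_config()].
#' @return `initial_lr * (1 - e/epochs)^lr_decay_power`.
#' @export
lr_at_epoch <- function(e, cfg) {
  if (any(e < 0 | e > cfg$epochs)) stop("epoch out of range")
  cfg$initial_lr * (1 - e / cfg$epochs)^cfg$lr_decay_power
}

#' Partition case ids into cross-validation folds
#'
#' @param case_ids Character or integer vector of ids.
#' @param k Number of folds; fold sizes differ by at most one.
#' @param seed RNG seed for the shuffle.
#' @return Named integer vector: fold index (1..k) per case id.
#' @export
make_folds <- function(case_ids, k, seed = 1L) {
  n <- length(case_ids)
  if (k > n) stop("more folds than cases")
  set.seed(seed)
  perm <- sample(n)
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), length.out = n)
  names(fold) <- as.character(case_ids)
  fold
}

#' Build and initialize a 3D U-Net model
#'
#' Weights use Xavier (uniform) initialization from the current RNG state;
#' batch-norm scale/shift start at 1/0 with running statistics at 0/1.
#' The model maps a `4 x E^3` input to an `n_classes x E^3` score grid for
#' any edge `E` divisible by `2^(levels-1)`.
#'
#' @param cfg A [unet_config()].
#' @return Object of class `unet_model`: list with `cfg`, trainable
#'   `params`, and batch-norm `state`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "unet_config"))
  ch <- channel_plan(cfg)
  L <- cfg$levels
  params <- list()
  state <- list()
  add_node <- function(pfx, cin, cout) {
    params[[paste0(pfx, "_W")]] <<- xavier_mat(cin * 27L, cout,
                                               cin * 27, cout * 27)
    params[[paste0(pfx, "_b")]] <<- numeric(cout)
    params[[paste0(pfx, "_g")]] <<- rep(1, cout)
    params[[paste0(pfx, "_be")]] <<- numeric(cout)
    state[[paste0(pfx, "_rm")]] <<- numeric(cout)
    state[[paste0(pfx, "_rv")]] <<- rep(1, cout)
  }
  for (l in seq_len(L)) {
    cin <- if (l == 1L) cfg$in_channels else ch[l - 1L]
    add_node(sprintf("enc%d_n1", l), cin, ch[l])
    add_node(sprintf("enc%d_n2", l), ch[l], ch[l])
  }
  for (l in rev(seq_len(L - 1))) {
    params[[sprintf("up%d_W", l)]] <- xavier_mat(ch[l + 1L], 8L * ch[l],
                                                 ch[l + 1L] * 8, ch[l] * 8)
    params[[sprintf("up%d_b", l)]] <- numeric(ch[l])
    add_node(sprintf("dec%d_n1", l), 2L * ch[l], ch[l])
    add_node(sprintf("dec%d_n2", l), ch[l], ch[l])
  }
  params$out_W <- xavier_mat(ch[1], cfg$n_classes, ch[1], cfg$n_classes)
  params$out_b <- numeric(cfg$n_classes)
  structure(list(cfg = cfg, params = params, state = state),
            class = "unet_model")
}

#' Number of trainable parameters
#'
#' @param model A `unet_model`.
#' @return Integer count over all weights, biases and batch-norm terms.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

check_edge <- function(d, levels) {
  f <- 2L^(levels - 1L)
  if (any(d %% f != 0L))
    stop("input extents ", paste(d, collapse = "x"),
         " not divisible by ", f)
}

#' Run the network on one stacked input
#'
#' Low-level forward pass used by training and inference; most callers
#' want [predict_case()].
#'
#' @param model A `unet_model`.
#' @param X `(B * prod(dims)) x in_channels` matrix.
#' @param dims Spatial extents, each divisible by `2^(levels-1)`.
#' @param B Number of stacked samples.
#' @param train Use batch statistics and keep the backward cache.
#' @return List with `scores` (`(B*nvox) x n_classes`), and in training
#'   mode `cache` and refreshed BN `state`.
#' @export
model_forward <- function(model, X, dims, B = 1L, train = FALSE) {
  check_edge(dims, model$cfg$levels)
  stopifnot(nrow(X) == B * prod(dims), ncol(X) == model$cfg$in_channels)
  unet_forward(model, X, as.integer(dims), as.integer(B), train = train)
}

case_to_matrix <- function(case) {
  shp <- dim(case$channels)
  matrix(case$channels, nrow = prod(shp[1:3]), ncol = shp[4])
}

#' Train one U-Net on a set of cases
#'
#' Patch-based training: per step, `batch_size` patches are drawn with the
#' lesion-biased center sampler, optionally augmented, stacked, and used
#' for one Adam update of the unweighted voxelwise cross-entropy under the
#' polynomial learning-rate schedule.  Fully reproducible from
#' `tcfg$seed`.
#'
#' @param cases List of [mpmri_case()] with labels (on-disk codes).
#' @param ucfg A [unet_config()].
#' @param tcfg A [train_config()].
#' @param pspec A [patch_spec()] (patch edge must be divisible by
#'   `2^(levels-1)`).
#' @param aspec An [augment_spec()], or NULL to disable augmentation.
#' @param normalize Z-score channels over the brain mask first (default).
#' @param verbose Print per-epoch loss.
#' @return List of class `trained_model`: `model`, `history` (data frame
#'   of epoch, lr, mean loss), and the configs.
#' @export
train_model <- function(cases, ucfg, tcfg, pspec = patch_spec(),
                        aspec = augment_spec(), normalize = TRUE,
                        verbose = FALSE) {
  codec <- label_codec(ucfg$n_classes)
  for (cs in cases) {
    if (is.null(cs$labels)) stop("training case without labels")
    bad <- setdiff(unique(as.vector(cs$labels)), codec$codes)
    if (length(bad))
      stop("case ", cs$case_id, " has label code(s) ",
           paste(bad, collapse = ","), " outside the ",
           ucfg$n_classes, "-class codec")
  }
  check_edge(rep(pspec$edge, 3L), ucfg$levels)
  if (normalize) cases <- lapply(cases, normalize_case)
  lesion_idx <- lapply(cases, function(cs) which(cs$labels != 0L))
  brain_idx <- lapply(cases, function(cs) which(cs$brain_mask))

  set.seed(tcfg$seed)
  model <- build_model(ucfg)
  opt <- adam_init(model$params)
  e3 <- pspec$edge^3
  B <- tcfg$batch_size
  iters <- max(1L, as.integer(ceiling(tcfg$patches_per_epoch / B)))
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        loss = numeric(0))
  for (ep in seq_len(tcfg$epochs) - 1L) {
    lr <- lr_at_epoch(ep, tcfg)
    ep_loss <- numeric(iters)
    for (it in seq_len(iters)) {
      X <- matrix(0, nrow = B * e3, ncol = ucfg$in_channels)
      y <- integer(B * e3)
      ci <- sample.int(length(cases), B, replace = TRUE)
      for (s in seq_len(B)) {
        cs <- cases[[ci[s]]]
        ctr <- sample_center(cs, pspec, lesion_idx[[ci[s]]],
                             brain_idx[[ci[s]]])
        p <- extract_patch(cs, ctr$center, pspec)
        if (!is.null(aspec)) p <- apply_augment(p, draw_augment(aspec))
        rows <- (s - 1L) * e3 + seq_len(e3)
        X[rows, ] <- matrix(p$image, nrow = e3)
        y[rows] <- encode_labels(as.vector(p$labels), codec)
      }
      fw <- unet_forward(model, X, rep(pspec$edge, 3L), B, train = TRUE)
      model$state <- fw$state
      l <- softmax_ce(fw$scores, y)
      ep_loss[it] <- l$loss
      grads <- unet_backward(model, fw$cache, l$grad,
                             rep(pspec$edge, 3L), B)
      up <- adam_step(model$params, grads, opt, lr)
      model$params <- up$params
      opt <- up$st
    }
    history <- rbind(history,
                     data.frame(epoch = ep, lr = lr, loss = mean(ep_loss)))
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f", ep, lr,
                      mean(ep_loss)))
  }
  structure(list(model = model, history = history, ucfg = ucfg,
                 tcfg = tcfg), class = "trained_model")
}

#' Train an ensemble of independently initialized models
#'
#' Members are trained with distinct seeds derived from `tcfg$seed`; their
#' softmax probabilities are averaged by [predict_case()].
#'
#' @inheritParams train_model
#' @return Object of class `trained_ensemble`: `members` (list of
#'   `trained_model`), configs, and per-member histories.
#' @export
train_ensemble <- function(cases, ucfg, tcfg, pspec = patch_spec(),
                           aspec = augment_spec(), normalize = TRUE,
                           verbose = FALSE) {
  set.seed(tcfg$seed)
  seeds <- sample.int(1000000000L, tcfg$ensemble_size)
  members <- lapply(seq_len(tcfg$ensemble_size), function(m) {
    tm <- tcfg
    tm$seed <- seeds[m]
    train_model(cases, ucfg, tm, pspec, aspec, normalize, verbose)
  })
  structure(list(members = members, ucfg = ucfg, tcfg = tcfg,
                 history = lapply(members, `[[`, "history")),
            class = "trained_ensemble")
}

as_member_list <- function(x) {
  if (inherits(x, "trained_ensemble")) lapply(x$members, `[[`, "model")
  else if (inherits(x, "trained_model")) list(x$model)
  else if (inherits(x, "unet_model")) list(x)
  else stop("expected a unet_model, trained_model or trained_ensemble")
}

#' Whole-volume inference with probability averaging
#'
#' The case is zero-padded so every extent is divisible by
#' `2^(levels-1)`, z-scored, and pushed through each ensemble member with
#' frozen batch-norm statistics.  Per-voxel softmax probabilities are
#' averaged across members, the argmax taken (ties to the lowest class
#' index), the result cropped back to the original shape and decoded to
#' on-disk label codes.
#'
#' @param ensemble A `trained_ensemble`, `trained_model` or `unet_model`.
#' @param case An [mpmri_case()].
#' @param codec Label codec; defaults to the model's class count.
#' @param normalize Z-score channels over the brain mask first (default).
#' @return List with `labels` (integer array of on-disk codes, original
#'   shape) and `prob` (4-D array `c(shape, n_classes)` of averaged
#'   probabilities).
#' @export
predict_case <- function(ensemble, case, codec = NULL, normalize = TRUE) {
  members <- as_member_list(ensemble)
  if (length(members) == 0L) stop("empty ensemble")
  cfg <- members[[1]]$cfg
  if (is.null(codec)) codec <- label_codec(cfg$n_classes)
  f <- 2L^(cfg$levels - 1L)
  padded <- pad_case(case, f)
  pc <- if (normalize) normalize_case(padded$case) else padded$case
  d <- dim(pc$channels)[1:3]
  X <- case_to_matrix(pc)
  P <- NULL
  for (m in members) {
    fw <- unet_forward(m, X, d, 1L, train = FALSE)
    Pm <- softmax_rows(fw$scores)
    P <- if (is.null(P)) Pm else P + Pm
  }
  P <- P / length(members)
  hard <- max.col(P, ties.method = "first") - 1L
  hard <- array(hard, dim = d)
  prob <- array(P, dim = c(d, cfg$n_classes))
  labels <- decode_labels(crop_case(hard, padded$record), codec)
  prob <- crop_case(prob, padded$record)
  list(labels = labels, prob = prob)
}

#' k-fold cross-validation training
#'
#' Trains one model per fold on the complement and predicts the held-out
#' cases, mirroring internal cross-validation at training time (distinct
#' from the independent retraining ensemble used for final inference).
#'
#' @inheritParams train_model
#' @param regions Regions to score on the held-out cases.
#' @return List with `folds` (assignment), `models` (per fold) and
#'   `reports` (row-bound [evaluate_case()] output for held-out cases).
#' @export
cross_validate <- function(cases, ucfg, tcfg, pspec = patch_spec(),
                           aspec = augment_spec(),
                           regions = c("WT", "TC", "ET"),
                           normalize = TRUE) {
  ids <- vapply(cases, `[[`, character(1), "case_id")
  fold <- make_folds(ids, tcfg$folds, tcfg$seed)
  models <- vector("list", tcfg$folds)
  reports <- list()
  for (k in seq_len(tcfg$folds)) {
    tr <- cases[fold != k]
    te <- cases[fold == k]
    tk <- tcfg
    tk$seed <- tcfg$seed + k
    models[[k]] <- train_model(tr, ucfg, tk, pspec, aspec, normalize)
    for (cs in te) {
      pred <- predict_case(models[[k]], cs)
      reports[[length(reports) + 1L]] <-
        evaluate_case(pred$labels, cs$labels, regions, cs$spacing,
                      case_id = cs$case_id)
    }
  }
  list(folds = fold, models = models, reports = do.call(rbind, reports))
}
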