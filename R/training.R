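# Training harness: SGD with momentum on per-pixel binary losses,
# fold-wise training with validation-IoU model selection, evaluation,
# and the ablation driver.

#' Training configuration
#'
#' @param learning_rate SGD learning rate (default 1e-2)
#' @param momentum classical momentum coefficient (default 0.9, no weight
#'   decay, no schedule)
#' @param epochs training epochs per fold (0 = return initial weights)
#' @param batch_size minibatch size
#' @param loss `"bce"` (binary cross-entropy, default), `"dice"` (soft
#'   Dice), or `"bce+dice"`
#' @param seed integer seed driving minibatch shuffling
#' @param threshold binarization threshold for validation/test masks
#' @return a `train_config`
#' @export
train_config <- function(learning_rate = 1e-2, momentum = 0.9, epochs = 10L,
                         batch_size = 4L, loss = c("bce", "dice", "bce+dice"),
                         seed = 1L, threshold = 0.5) {
  loss <- match.arg(loss)
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (epochs < 0) stop("epochs must be >= 0")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = loss,
                 seed = as.integer(seed), threshold = threshold),
            class = "train_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# loss value and gradient w.r.t. logits, both averaged over all pixels
loss_and_grad <- function(logits, y, loss) {
  m <- length(logits)
  p <- sigmoid(logits)
  out <- list(value = 0, grad = 0)
  if (loss %in% c("bce", "bce+dice")) {
    # numerically stable: max(z,0) - z*y + log(1+exp(-|z|))
    v <- mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
    out$value <- out$value + v
    out$grad <- out$grad + (p - y) / m
  }
  if (loss %in% c("dice", "bce+dice")) {
    s <- 1
    num <- 2 * sum(p * y) + s
    den <- sum(p) + sum(y) + s
    out$value <- out$value + (1 - num / den)
    dLdp <- -(2 * y * den - num) / den^2
    out$grad <- out$grad + dLdp * p * (1 - p)
  }
  out
}

#' Train a segmentation network over cross-validation folds
#'
#' For each requested fold the initial network is cloned and trained with
#' SGD on the fold's training indices; after every epoch the fold's
#' validation IoU is measured (running batch-norm statistics, thresholded
#' predictions) and the best-validation-IoU state is kept. Fully
#' deterministic under a fixed config seed. `epochs = 0` returns the
#' initial parameters untouched.
#'
#' @param network a `segmentation_network` providing the initial weights
#' @param splits a [make_splits()] plan
#' @param data a `seg_dataset` covering the split indices
#' @param cfg a [train_config()]
#' @param folds which folds to train (default all five)
#' @param verbose print one structured log line per epoch
#' @return a `train_result`: `networks` (one per trained fold, at the
#'   best-validation checkpoint), `history` (fold/epoch loss and
#'   validation IoU), `folds`, `config`
#' @export
train <- function(network, splits, data, cfg, folds = seq_along(splits$folds),
                  verbose = FALSE) {
  stopifnot(inherits(network, "segmentation_network"),
            inherits(splits, "split_plan"), inherits(cfg, "train_config"))
  if (max(unlist(lapply(splits$folds, `[[`, "train"))) > length(data$images))
    stop("split plan indices exceed the dataset size")
  set.seed(cfg$seed)
  history <- list()
  networks <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    k <- folds[fi]
    tr_idx <- splits$folds[[k]]$train
    va_idx <- splits$folds[[k]]$val
    if (length(tr_idx) == 0L) stop("empty training fold ", k)
    net <- nn_clone(network)
    best <- list(iou = -Inf, state = nn_state(net$net))
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      nb <- ceiling(length(ord) / cfg$batch_size)
      ep_loss <- 0
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size,
                                                      length(ord))]
        batch <- dataset_batch(data, idx)
        logits <- nn_forward(net$net, batch$x, training = TRUE)
        lg <- loss_and_grad(logits, batch$y, cfg$loss)
        if (!is.finite(lg$value))
          stop("training diverged: non-finite loss at fold ", k,
               ", epoch ", ep, ", batch ", b)
        ep_loss <- ep_loss + lg$value * length(idx)
        g <- array(lg$grad, dim = dim(logits))
        nn_backward(net$net, g)
        sgd_step(net$net, cfg$learning_rate, cfg$momentum)
      }
      ep_loss <- ep_loss / length(ord)
      ev <- evaluate(net, data, va_idx, threshold = cfg$threshold,
                     metrics = "iou")
      if (ev$iou > best$iou) best <- list(iou = ev$iou,
                                          state = nn_state(net$net))
      history[[length(history) + 1L]] <-
        data.frame(fold = k, epoch = ep, loss = ep_loss, val_iou = ev$iou)
      if (verbose)
        message(sprintf("fold=%d epoch=%d loss=%.5f val_iou=%.4f",
                        k, ep, ep_loss, ev$iou))
    }
    if (cfg$epochs > 0L) nn_load_state(net$net, best$state)
    networks[[fi]] <- net
  }
  structure(list(networks = networks, folds = folds,
                 history = if (length(history)) do.call(rbind, history)
                           else data.frame(fold = integer(), epoch = integer(),
                                           loss = numeric(),
                                           val_iou = numeric()),
                 config = cfg),
            class = "train_result")
}

#' Evaluate a network on dataset indices
#'
#' Pixel confusion counts are pooled over all evaluated images
#' (micro-average) after thresholding the probability maps; AUC is
#' computed on the raw probabilities against the pooled ground truth.
#'
#' @param network a `segmentation_network`
#' @param data a `seg_dataset`
#' @param indices image indices to evaluate (non-empty)
#' @param threshold binarization threshold (default 0.5)
#' @param metrics which metrics to compute; any of `"iou"`, `"dice"`,
#'   `"precision"`, `"auc"`
#' @param batch_size forward-pass batch size
#' @return list with the requested metrics plus the pooled
#'   `confusion_counts`
#' @export
evaluate <- function(network, data, indices, threshold = 0.5,
                     metrics = c("iou", "dice", "precision", "auc"),
                     batch_size = 4L) {
  if (length(indices) == 0L) stop("empty evaluation index set")
  metrics <- match.arg(metrics, several.ok = TRUE)
  tp <- fp <- fn <- tn <- 0
  want_auc <- "auc" %in% metrics
  probs <- if (want_auc) vector("list", ceiling(length(indices) / batch_size))
  truths <- probs
  bi <- 0L
  for (start in seq(1, length(indices), by = batch_size)) {
    idx <- indices[start:min(start + batch_size - 1, length(indices))]
    batch <- dataset_batch(data, idx)
    p <- network_forward(network, batch$x, training = FALSE)
    pm <- as.numeric(p >= threshold)
    y <- as.numeric(batch$y)
    tp <- tp + sum(pm == 1 & y == 1)
    fp <- fp + sum(pm == 1 & y == 0)
    fn <- fn + sum(pm == 0 & y == 1)
    tn <- tn + sum(pm == 0 & y == 0)
    if (want_auc) {
      bi <- bi + 1L
      probs[[bi]] <- as.numeric(p); truths[[bi]] <- y
    }
  }
  cc <- structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
                  class = "confusion_counts")
  out <- list(confusion = cc)
  if ("iou" %in% metrics) out$iou <- iou(cc)
  if ("dice" %in% metrics) out$dice <- dice(cc)
  if ("precision" %in% metrics) out$precision <- precision(cc)
  if (want_auc)
    out$auc <- roc_auc(unlist(probs), unlist(truths))
  out
}

#' Pairwise comparison of per-fold results
#'
#' Runs the independent two-sample t test ([two_sample_t_test()]) on two
#' vectors of per-fold metric values and annotates which mean is higher.
#'
#' @param a,b numeric vectors of per-fold values (>= 2 each)
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b`, `higher`
#' @export
compare <- function(a, b) {
  if (inherits(a, "metric_report")) a <- a$values
  if (inherits(b, "metric_report")) b <- b$values
  tt <- two_sample_t_test(a, b)
  c(tt, list(mean_a = mean(a), mean_b = mean(b),
             higher = if (mean(a) > mean(b)) "a"
                      else if (mean(b) > mean(a)) "b" else "tie"))
}

#' Run an ablation over named architectures
#'
#' Trains every requested architecture on identical data, splits and
#' seed, evaluates each trained fold on the held-out test subset and
#' reports mean ± SD of the test IoU over folds. The run is resumable:
#' with `out_dir` set, completed rows are written as JSON and skipped on
#' rerun. Unknown names produce a recorded failure row and the run
#' continues.
#'
#' @param config_names architecture registry names
#'   ([build_architecture()]), block shorthands like `"msunet:39"`, or
#'   the keyword `"all31"` expanding to the full parallel block family
#' @param style a [synthetic_style()] or style name
#' @param cfg a [train_config()]
#' @param seed seed for data generation, splitting and initialization
#' @param n dataset size
#' @param levels,base_width network dimensions for every row
#' @param folds folds to train per architecture
#' @param out_dir optional directory for resumable per-row JSON results
#' @return an `ablation_result`: `table` (data.frame with name,
#'   mean/sd IoU, error), `fold_values` (named list), `best` (row name
#'   with the highest mean IoU)
#' @export
run_ablation <- function(config_names, style, cfg, seed = 1L, n = 30L,
                         levels = 3L, base_width = 8L, folds = 1:5,
                         out_dir = NULL) {
  if (is.character(style)) style <- synthetic_style(style)
  if ("all31" %in% config_names) {
    all31 <- paste0("msunet:", names(enumerate_block_configs()))
    config_names <- c(setdiff(config_names, "all31"), all31)
  }
  data <- synthesize_dataset(style, n, seed)
  splits <- make_splits(n, seed)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  rows <- list(); fold_values <- list()
  for (nm in config_names) {
    cache <- if (!is.null(out_dir))
      file.path(out_dir, paste0(gsub("[^A-Za-z0-9]", "_", nm), ".json"))
    if (!is.null(cache) && file.exists(cache)) {
      r <- jsonlite::read_json(cache, simplifyVector = TRUE)
      rows[[nm]] <- data.frame(name = nm, mean_iou = r$mean_iou,
                               sd_iou = r$sd_iou, error = NA_character_)
      fold_values[[nm]] <- r$fold_iou
      next
    }
    res <- tryCatch({
      net <- build_architecture(nm, levels = levels, base_width = base_width,
                                in_channels = style$channels, seed = seed)
      tr <- train(net, splits, data, cfg, folds = folds)
      fold_iou <- vapply(tr$networks, function(nw)
        evaluate(nw, data, splits$test, threshold = cfg$threshold,
                 metrics = "iou")$iou, numeric(1))
      list(fold_iou = fold_iou)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[nm]] <- data.frame(name = nm, mean_iou = NA_real_,
                               sd_iou = NA_real_,
                               error = conditionMessage(res))
      next
    }
    rep <- aggregate_folds(res$fold_iou, "IoU")
    rows[[nm]] <- data.frame(name = nm, mean_iou = rep$mean, sd_iou = rep$sd,
                             error = NA_character_)
    fold_values[[nm]] <- res$fold_iou
    if (!is.null(cache))
      jsonlite::write_json(list(name = nm, mean_iou = rep$mean,
                                sd_iou = rep$sd, fold_iou = res$fold_iou),
                           cache, auto_unbox = TRUE, digits = NA)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  ok <- !is.na(table$mean_iou)
  best <- if (any(ok)) table$name[ok][which.max(table$mean_iou[ok])]
          else NA_character_
  table$best <- table$name == best & !is.na(table$mean_iou)
  structure(list(table = table, fold_values = fold_values, best = best),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("ablation over", nrow(x$table), "configurations (test IoU, mean ± SD over folds)\n")
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    if (is.na(r$mean_iou))
      cat(sprintf("  %-24s FAILED: %s\n", r$name, r$error))
    else
      cat(sprintf("  %-24s %.4f ± %.4f%s\n", r$name, r$mean_iou, r$sd_iou,
                  if (isTRUE(r$best)) "  <- best" else ""))
  }
  invisible(x)
}

#' Desk-scale end-to-end benchmark
#'
#' The package's standard single-CPU check that the pipeline learns:
#' MSU-Net(37) at `base_width` 16 and 4 levels is trained on the blobs
#' dataset (n = 120 at 64 x 64) for 15 epochs on one cross-validation
#' fold, then scored on the held-out test subset alongside the untrained
#' initial network.
#'
#' @param seed seed for data, splits and initialization
#' @param epochs,n,image_size,base_width,levels,batch_size protocol knobs
#' @param arch architecture registry name
#' @param verbose print per-epoch log lines
#' @return list with `test_iou`, `test_dice`, `test_auc`,
#'   `untrained_iou`, `history`, `params`
#' @export
run_smoke_benchmark <- function(seed = 1L, epochs = 15L, n = 120L,
                                image_size = 64L, base_width = 16L,
                                levels = 4L, batch_size = 4L,
                                arch = "msunet", verbose = FALSE) {
  style <- synthetic_style("blobs", image_size = image_size)
  data <- synthesize_dataset(style, n, seed)
  splits <- make_splits(n, seed)
  net0 <- build_architecture(arch, levels = levels, base_width = base_width,
                             in_channels = style$channels, seed = seed)
  cfg <- train_config(epochs = epochs, batch_size = batch_size, seed = seed)
  base_ev <- evaluate(net0, data, splits$test, metrics = c("iou"))
  tr <- train(net0, splits, data, cfg, folds = 1L, verbose = verbose)
  ev <- evaluate(tr$networks[[1]], data, splits$test)
  list(test_iou = ev$iou, test_dice = ev$dice, test_precision = ev$precision,
       test_auc = ev$auc, untrained_iou = base_ev$iou,
       history = tr$history, params = n_parameters(net0$net))
}
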