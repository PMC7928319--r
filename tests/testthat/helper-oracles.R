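# Independent oracles used across test files; deliberately naive so they
# share no code with the implementation.

# per-pixel confusion loop
loop_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    else if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# Mann-Whitney pairwise fraction (ties count 1/2)
pairwise_auc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
  tot / (length(pos) * length(neg))
}

# closed-form parameter count of one conv (+ optional bias / batch-norm)
conv_params <- function(k, cin, cout, bias = TRUE, bn = TRUE) {
  k * k * cin * cout + (if (bias) cout else 0) + (if (bn) 2 * cout else 0)
}

rand_input <- function(h, w, c, n = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(rnorm(h * w * c * n), dim = c(h, w, c, n))
}
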