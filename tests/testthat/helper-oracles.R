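# Independent brute-force oracles used to freeze expected values.
# These deliberately share no code with the implementation.

# AUROC by exhaustive pair counting (ties count 1/2).
oracle_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Average precision by direct enumeration over distinct thresholds.
oracle_average_precision <- function(scores, labels) {
  labels <- as.logical(labels)
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels)
  prev_recall <- 0
  ap <- 0
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels)
    prec <- tp / sum(pred)
    rec <- tp / n_pos
    ap <- ap + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  ap
}

# Youden threshold by plain loop with lowest-threshold tie-break.
oracle_youden <- function(probs, truth, cands = 1:99) {
  truth <- as.logical(truth)
  best_j <- -Inf
  best_t <- NA
  for (t in sort(cands)) {
    pred <- probs >= t / 100
    j <- sum(pred & truth) / sum(truth) - sum(pred & !truth) / sum(!truth)
    if (j > best_j + 1e-12) {
      best_j <- j
      best_t <- t
    }
  }
  best_t
}

# Policy-constrained threshold by full enumeration: highest t with model
# FNR strictly below physician FNR in every group.
oracle_policy <- function(probs, truth, phys, group, cands = 1:99) {
  truth <- as.logical(truth)
  feasible <- c()
  for (t in cands) {
    ok <- TRUE
    for (g in unique(group)) {
      i <- group == g
      pos <- i & truth
      if (!any(pos)) next
      m_fnr <- mean(probs[pos] < t / 100)
      p_fnr <- mean(!phys[pos])
      if (!(m_fnr < p_fnr)) ok <- FALSE
    }
    if (ok) feasible <- c(feasible, t)
  }
  if (!length(feasible)) NA else max(feasible)
}

# DOR by direct arithmetic, 0.5 added everywhere when any cell is zero.
oracle_dor <- function(tp, fp, fn, tn) {
  if (any(c(tp, fp, fn, tn) == 0)) {
    tp <- tp + 0.5; fp <- fp + 0.5; fn <- fn + 0.5; tn <- tn + 0.5
  }
  (tp / fn) / (fp / tn)
}
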