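# Fixtures and independent oracle implementations used across the suite.
# Oracles are deliberately naive (explicit loops, no shared code with the
# package internals they check).

# ---- tiny hand-built corpus fixtures --------------------------------------

minimal_corpus_xml <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n<corpus>\n',
    '  <document id="d1">\n',
    '    <sentence id="d1.s0" text="aspirin increases the effect of warfarin">\n',
    '      <entity id="d1.s0.e0" charOffset="0-6" type="drug" text="aspirin"/>\n',
    '      <entity id="d1.s0.e1" charOffset="32-39" type="drug" text="warfarin"/>\n',
    '      <pair id="d1.s0.p0" e1="d1.s0.e0" e2="d1.s0.e1" ddi="true" type="effect"/>\n',
    '    </sentence>\n',
    '  </document>\n</corpus>\n')
}

# a sentence object with mentions located by exact surface match
make_test_sentence <- function(text, surfaces, pairs, id = "s1") {
  mentions <- lapply(seq_along(surfaces), function(i) {
    st <- regexpr(surfaces[i], text, fixed = TRUE)
    stopifnot(st > 0)
    list(id = paste0("e", i), text = surfaces[i],
         spans = matrix(c(st - 1L, st - 1L + nchar(surfaces[i])), 1L, 2L,
                        dimnames = list(NULL, c("start", "end"))),
         discontinuous = FALSE)
  })
  prs <- lapply(seq_along(pairs), function(j)
    list(id = paste0("p", j), e1 = pairs[[j]][1], e2 = pairs[[j]][2],
         label = pairs[[j]][3]))
  list(id = id, text = text, mentions = mentions, pairs = prs)
}

# ---- numeric oracles -------------------------------------------------------

oracle_softmax <- function(o) {
  # log-sum-exp route, independent of the package's implementation
  lse <- max(o) + log(sum(exp(o - max(o))))
  exp(o - lse)
}

oracle_conv <- function(X, W, b) {
  # triple-loop convolution with ReLU; W is (w*D) x m
  D <- ncol(X)
  w <- nrow(W) / D
  L <- nrow(X) - w + 1
  m <- ncol(W)
  out <- matrix(0, L, m)
  for (i in seq_len(L)) {
    for (f in seq_len(m)) {
      acc <- b[f]
      for (j in seq_len(w)) {
        for (dd in seq_len(D)) {
          acc <- acc + W[(j - 1) * D + dd, f] * X[i + j - 1, dd]
        }
      }
      out[i, f] <- max(acc, 0)
    }
  }
  out
}

# zero-filled block of a feature-matrix object
oracle_block <- function(fm, i, rows) {
  H <- fm$blocks[[i]]
  if (rows == "all" && nrow(H) < fm$n)
    H <- rbind(H, matrix(0, fm$n - nrow(H), ncol(H)))
  H
}

oracle_pool_max <- function(fm, rows = "all") {
  z <- c()
  for (i in seq_along(fm$blocks)) {
    H <- oracle_block(fm, i, rows)
    for (f in seq_len(ncol(H))) {
      best <- -Inf
      for (r in seq_len(nrow(H))) if (H[r, f] > best) best <- H[r, f]
      z <- c(z, best)
    }
  }
  z
}

oracle_pool_avg <- function(fm, rows = "all") {
  z <- c()
  for (i in seq_along(fm$blocks)) {
    H <- oracle_block(fm, i, rows)
    for (f in seq_len(ncol(H))) z <- c(z, sum(H[, f]) / nrow(H))
  }
  z
}

oracle_pool_attentive <- function(fm, w_alpha, rows = "all") {
  # explicit three-step route: tanh, softmax by hand, weighted sum
  z <- c()
  for (i in seq_along(fm$blocks)) {
    S <- oracle_block(fm, i, rows)
    M <- tanh(S)
    a <- as.numeric(M %*% w_alpha[[i]])
    alpha <- exp(a) / sum(exp(a))
    z <- c(z, tanh(as.numeric(t(S) %*% alpha)))
  }
  z
}

# a random feature-matrix object (raw score blocks, not necessarily >= 0,
# so the pooling operators are exercised beyond the ReLU range)
random_fm <- function(n = 10, m = 4, widths = c(2, 4)) {
  blocks <- lapply(widths, function(w)
    matrix(stats::rnorm((n - w + 1) * m), n - w + 1, m))
  names(blocks) <- as.character(widths)
  structure(list(blocks = blocks, widths = as.integer(widths),
                 valid = as.integer(n - widths + 1), n = as.integer(n),
                 m = as.integer(m)),
            class = "ddi_fm")
}

# ---- tiny model builders ---------------------------------------------------

tiny_model <- function(pooling = "max", scope = "block", vocab_size = 12L,
                       n = 8L, m_e = 6L, m_d = 2L, widths = c(2L, 3L),
                       m = 3L, dropout = 0) {
  cfgE <- ddi_encoder_config(n = n, m_e = m_e, m_d = m_d)
  cfg <- ddipool:::model_config(cfgE, widths = widths, n_filters = m,
                                pooling = pooling, attention_scope = scope,
                                dropout = dropout)
  params <- ddipool:::ddi_params_init(vocab_size, cfg)
  # non-zero softmax weights so every gradient path is exercised
  params$W_s <- matrix(stats::runif(length(params$W_s), -0.3, 0.3),
                       nrow(params$W_s))
  params$d <- stats::runif(length(params$d), -0.1, 0.1)
  list(cfg = cfg, params = params, cfgE = cfgE, vocab_size = vocab_size)
}

random_encoded <- function(n = 8L, vocab_size = 12L) {
  p1 <- sample(n - 2L, 1L)
  p2 <- p1 + sample(2L, 1L)
  len <- max(p2, sample(3:n, 1L))
  pad <- function(x) c(x, rep(0L, n - len))
  structure(list(
    word_ids = c(sample(3:vocab_size, len, replace = TRUE),
                 rep(1L, n - len)),
    pos1_ids = pad(ddi_regroup(seq_len(len) - p1, n)),
    pos2_ids = pad(ddi_regroup(seq_len(len) - p2, n)),
    label_id = sample(5L, 1L), p1 = p1, p2 = p2,
    pad_start = len + 1L, sentence_id = "s", pair_id = "p"),
    class = "ddi_encoded")
}

# ---- finite-difference gradients ------------------------------------------

flat_param_paths <- function(obj, path = c()) {
  if (is.list(obj))
    unlist(lapply(seq_along(obj), function(i)
      flat_param_paths(obj[[i]], c(path, i))), recursive = FALSE)
  else list(path)
}

numeric_gradient <- function(enc, params, cfg, eps = 1e-5) {
  loss_at <- function(p) {
    fw <- ddipool:::cnn_forward(enc, p, cfg, NULL)
    -log(fw$probs[enc$label_id])
  }
  out <- list()
  for (pth in flat_param_paths(params)) {
    leaf <- params[[pth]]
    g <- leaf * 0
    for (i in seq_along(leaf)) {
      p2 <- params; x <- p2[[pth]]; x[i] <- x[i] + eps; p2[[pth]] <- x
      up <- loss_at(p2)
      p2 <- params; x <- p2[[pth]]; x[i] <- x[i] - eps; p2[[pth]] <- x
      dn <- loss_at(p2)
      g[i] <- (up - dn) / (2 * eps)
    }
    out[[paste(pth, collapse = "/")]] <- g
  }
  out
}

max_grad_relerr <- function(enc, params, cfg) {
  fw <- ddipool:::cnn_forward(enc, params, cfg, NULL)
  do <- fw$probs
  do[enc$label_id] <- do[enc$label_id] - 1
  ga <- ddipool:::cnn_backward(fw, enc, params, cfg, do)
  gn <- numeric_gradient(enc, params, cfg)
  worst <- 0
  for (pth in flat_param_paths(params)) {
    a <- ga[[pth]]
    b <- gn[[paste(pth, collapse = "/")]]
    re <- sqrt(sum((a - b)^2)) /
      max(sqrt(sum(a^2)), sqrt(sum(b^2)), 1e-8)
    worst <- max(worst, re)
  }
  worst
}

# ---- evaluation oracle -----------------------------------------------------

oracle_score <- function(gold_labels, pred_labels) {
  pos <- c("mechanism", "effect", "advice", "int")
  rows <- list()
  tot <- c(TP = 0, FP = 0, FN = 0)
  for (cl in pos) {
    tp <- fp <- fn <- 0
    for (i in seq_along(gold_labels)) {
      if (gold_labels[i] == cl && pred_labels[i] == cl) tp <- tp + 1
      if (gold_labels[i] != cl && pred_labels[i] == cl) fp <- fp + 1
      if (gold_labels[i] == cl && pred_labels[i] != cl) fn <- fn + 1
    }
    rows[[cl]] <- c(TP = tp, FP = fp, FN = fn)
    tot <- tot + c(tp, fp, fn)
  }
  rows$overall <- tot
  lapply(rows, function(x) {
    p <- if (x["TP"] + x["FP"] > 0) x[["TP"]] / (x[["TP"]] + x[["FP"]]) else 0
    r <- if (x["TP"] + x["FN"] > 0) x[["TP"]] / (x[["TP"]] + x[["FN"]]) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(x, precision = p, recall = r, f1 = f)
  })
}
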