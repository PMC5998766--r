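# Model fitting: the ddi_cnn() entry point, mini-batch Adam with the
# max-norm constraint on the softmax weights, and the S3 methods of the
# fitted-model object.

# ---- parameter-tree arithmetic --------------------------------------------

tree_zero <- function(x) {
  if (is.list(x)) lapply(x, tree_zero) else x * 0
}

tree_add <- function(a, b) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- tree_add(a[[i]], b[[i]])
    a
  } else a + b
}

tree_scale <- function(a, s) {
  if (is.list(a)) lapply(a, tree_scale, s = s) else a * s
}

# one Adam update over parallel trees; returns list(params, m, v)
adam_step <- function(params, grads, m, v, lr, b1, b2, eps, t) {
  corr <- lr * sqrt(1 - b2^t) / (1 - b1^t)
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      for (i in seq_along(p)) {
        r <- rec(p[[i]], g[[i]], m[[i]], v[[i]])
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      list(p = p - corr * m / (sqrt(v) + eps), m = m, v = v)
    }
  }
  r <- rec(params, grads, m, v)
  list(params = r$p, m = r$m, v = r$v)
}

# rescale columns of W_s whose Euclidean norm exceeds the bound
enforce_maxnorm <- function(W_s, bound) {
  nrm <- sqrt(colSums(W_s^2))
  over <- nrm > bound
  if (any(over))
    W_s[, over] <- sweep(W_s[, over, drop = FALSE], 2L,
                         bound / nrm[over], "*")
  W_s
}

# ---- training control ------------------------------------------------------

#' Training and architecture control parameters
#'
#' Defaults follow the architecture's published configuration where one is
#' stated (mini-batch size 50, dropout 0.5, softmax-weight norm bound 3,
#' filter widths 2/4/6, 200 filters per width) and the Adam update rule's
#' standard moments where the source is silent.
#'
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the shuffled training set.
#' @param lr,beta1,beta2,eps Adam step size and moment parameters.
#' @param dropout Dropout probability `p` on the pooled vector.
#' @param l2 The softmax-weight regularisation strength: with
#'   `l2_mode = "maxnorm"` (default) each column of `W_s` is rescaled to
#'   Euclidean norm `l2` whenever it exceeds it after an update; with
#'   `l2_mode = "penalty"` it is an additive coefficient on `||W_s||^2`.
#' @param l2_mode `"maxnorm"` or `"penalty"`.
#' @param widths Integer vector of convolution window sizes.
#' @param n_filters Filters per window size (`m`).
#' @param attention_scope `"block"` (one attention per window-size block,
#'   pooled length `m*k`) or `"stacked"` (single attention over the stacked
#'   feature matrix, pooled length `m`).
#' @param pool_rows `"all"` to pool over every row of the zero-filled
#'   blocks, `"valid"` to restrict to the `n-w+1` computed rows.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout; two fits with the same seed are bitwise identical.
#' @param verbose Print the per-epoch loss.
#' @return List of class `ddi_control`.
#' @export
ddi_control <- function(batch_size = 50L, epochs = 10L, lr = 1e-3,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                        dropout = 0.5, l2 = 3,
                        l2_mode = c("maxnorm", "penalty"),
                        widths = c(2L, 4L, 6L), n_filters = 200L,
                        attention_scope = c("block", "stacked"),
                        pool_rows = c("all", "valid"),
                        seed = 1L, verbose = FALSE) {
  stopifnot(batch_size >= 1, epochs >= 0, dropout >= 0, dropout < 1,
            l2 > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr, beta1 = beta1,
                 beta2 = beta2, eps = eps, dropout = dropout, l2 = l2,
                 l2_mode = match.arg(l2_mode),
                 widths = as.integer(widths),
                 n_filters = as.integer(n_filters),
                 attention_scope = match.arg(attention_scope),
                 pool_rows = match.arg(pool_rows),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "ddi_control")
}

# ---- loss ------------------------------------------------------------------

# mean negative log-likelihood of a list of encoded instances (no dropout
# unless masks supplied); adds the additive l2 penalty when configured
batch_loss <- function(encoded, params, cfg, masks = NULL,
                       l2 = 0, l2_mode = "maxnorm") {
  nll <- vapply(seq_along(encoded), function(i) {
    fw <- cnn_forward(encoded[[i]], params, cfg,
                      if (is.null(masks)) NULL else masks[[i]])
    -log(fw$probs[encoded[[i]]$label_id])
  }, 0)
  loss <- mean(nll)
  if (l2_mode == "penalty") loss <- loss + l2 * sum(params$W_s^2)
  loss
}

#' Mean negative log-likelihood of a fitted model on encoded data
#'
#' The training objective: the mean over instances of
#' `-log p(y | x, theta)`, with `p` the softmax class probability. A model
#' predicting the uniform distribution scores `log 5 ~ 1.609` per instance.
#' Evaluated without dropout.
#'
#' @param object A fitted [ddi_cnn()] model.
#' @param instances List of kept `ddi_instance` objects (encoded with the
#'   model's vocabulary), or a list of `ddi_encoded`.
#' @return Scalar mean negative log-likelihood.
#' @export
ddi_loss <- function(object, instances) {
  stopifnot(inherits(object, "ddi_cnn"))
  enc <- if (length(instances) && inherits(instances[[1]], "ddi_encoded"))
    instances else ddi_encode_set(instances, object$vocab, object$config)
  if (!length(enc)) stop("no encodable instances")
  batch_loss(enc, object$params, object$model_config,
             l2 = object$control$l2, l2_mode = object$control$l2_mode)
}

# ---- the fitting function --------------------------------------------------

#' Fit the convolutional DDI classifier
#'
#' Trains a convolutional sentence classifier over word and position
#' embeddings for the five-way DDI label set. The input sentences are
#' blinded candidate-pair instances; the network embeds each token together
#' with its regrouped relative positions to the two target drugs, applies
#' filter banks of several window widths, reduces the stacked score matrix
#' with the chosen pooling operator, and scores the pooled vector with a
#' dropout-regularised softmax. Training minimises the negative
#' log-likelihood with Adam over shuffled mini-batches; after every update
#' the softmax weight columns are constrained to the configured norm bound.
#'
#' @param x A `ddi_corpus` (it is prepared with `rules`), a `ddi_dataset`
#'   from [ddi_prepare()], or a list of kept `ddi_instance` objects.
#' @param pooling `"max"`, `"avg"`, `"attentive"`, or `"combined"`
#'   (max + attentive over two separate filter banks, pooled vectors
#'   concatenated, trained jointly).
#' @param config [ddi_encoder_config()]: maximum length and embedding
#'   dimensions.
#' @param control [ddi_control()]: optimisation and architecture settings.
#' @param rules [ddi_filter_rules()] used when `x` is a corpus, or `NULL`
#'   to skip negative filtering.
#' @return Object of class `ddi_cnn` with components `params` (all
#'   trainable tensors), `vocab`, `config`, `model_config`, `control`,
#'   `pooling`, `rules`, `classes`, `trace` (per-epoch mean training
#'   loss), `initial_loss` and `n_train`. Methods: `print`, `summary`,
#'   `coef`, `predict`, `plot`.
#' @examples
#' syn <- ddi_synthetic_corpus(60, seed = 42)
#' fit <- ddi_cnn(syn$corpus, pooling = "max",
#'                config = ddi_encoder_config(n = 40, m_e = 20, m_d = 3),
#'                control = ddi_control(epochs = 2, n_filters = 8,
#'                                      widths = c(2, 3), seed = 1))
#' fit
#' head(predict(fit, syn$corpus))
#' @export
ddi_cnn <- function(x, pooling = c("max", "avg", "attentive", "combined"),
                    config = ddi_encoder_config(),
                    control = ddi_control(),
                    rules = ddi_filter_rules()) {
  pooling <- match.arg(pooling)
  cl <- match.call()
  if (inherits(x, "ddi_corpus")) x <- ddi_prepare(x, rules)
  instances <- if (inherits(x, "ddi_dataset")) x$kept else x
  if (!length(instances)) stop("no kept training instances")
  vocab <- ddi_vocab(instances)
  cfg <- model_config(config, widths = control$widths,
                      n_filters = control$n_filters, pooling = pooling,
                      attention_scope = control$attention_scope,
                      pool_rows = control$pool_rows,
                      dropout = control$dropout)
  enc <- ddi_encode_set(instances, vocab, config)
  if (!length(enc)) stop("no encodable training instances")

  set.seed(control$seed)
  params <- ddi_params_init(length(vocab), cfg)
  initial_loss <- batch_loss(enc, params, cfg)

  mstate <- tree_zero(params)
  vstate <- tree_zero(params)
  N <- length(enc)
  pd <- pooled_dim(cfg)
  step <- 0L
  trace <- data.frame(epoch = integer(0), loss = numeric(0))
  for (ep in seq_len(control$epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, N, by = control$batch_size)) {
      idx <- ord[start:min(start + control$batch_size - 1L, N)]
      grads <- tree_zero(params)
      bl <- 0
      for (i in idx) {
        mask <- if (control$dropout > 0)
          stats::rbinom(pd, 1L, 1 - control$dropout) else NULL
        fw <- cnn_forward(enc[[i]], params, cfg, mask)
        y <- enc[[i]]$label_id
        bl <- bl - log(fw$probs[y])
        do <- fw$probs
        do[y] <- do[y] - 1
        grads <- tree_add(grads, cnn_backward(fw, enc[[i]], params, cfg, do))
      }
      grads <- tree_scale(grads, 1 / length(idx))
      if (control$l2_mode == "penalty")
        grads$W_s <- grads$W_s + 2 * control$l2 * params$W_s
      bl <- bl / length(idx)
      if (!is.finite(bl))
        stop("training diverged (non-finite loss) at epoch ", ep)
      step <- step + 1L
      upd <- adam_step(params, grads, mstate, vstate, control$lr,
                       control$beta1, control$beta2, control$eps, step)
      params <- upd$params; mstate <- upd$m; vstate <- upd$v
      if (control$l2_mode == "maxnorm")
        params$W_s <- enforce_maxnorm(params$W_s, control$l2)
      ep_loss <- ep_loss + bl
      nb <- nb + 1L
    }
    trace <- rbind(trace, data.frame(epoch = ep, loss = ep_loss / max(nb, 1L)))
    if (control$verbose)
      message(sprintf("epoch %d  mean loss %.4f", ep, ep_loss / max(nb, 1L)))
  }

  structure(list(params = params, vocab = vocab, config = config,
                 model_config = cfg, control = control, pooling = pooling,
                 rules = rules, classes = DDI_CLASSES, trace = trace,
                 initial_loss = initial_loss, n_train = N, call = cl),
            class = "ddi_cnn")
}

# ---- methods ---------------------------------------------------------------

#' @export
print.ddi_cnn <- function(x, ...) {
  cat("Convolutional DDI classifier (", x$pooling, " pooling)\n", sep = "")
  cat("  n =", x$config$n, " m_e =", x$config$m_e, " m_d =", x$config$m_d,
      " widths =", paste(x$model_config$widths, collapse = "/"),
      " filters/width =", x$model_config$m, "\n")
  cat("  vocabulary:", length(x$vocab), "  training instances:",
      x$n_train, "\n")
  if (nrow(x$trace))
    cat(sprintf("  loss: %.4f (initial %.4f) after %d epoch(s)\n",
                x$trace$loss[nrow(x$trace)], x$initial_loss,
                nrow(x$trace)))
  invisible(x)
}

#' @export
summary.ddi_cnn <- function(object, ...) {
  count <- function(t) if (is.list(t)) sum(vapply(t, count, 0)) else length(t)
  out <- list(pooling = object$pooling, config = object$config,
              n_parameters = count(object$params),
              pooled_dim = pooled_dim(object$model_config),
              trace = object$trace, initial_loss = object$initial_loss,
              n_train = object$n_train,
              ws_col_norms = sqrt(colSums(object$params$W_s^2)))
  class(out) <- "summary.ddi_cnn"
  out
}

#' @export
print.summary.ddi_cnn <- function(x, ...) {
  cat("Convolutional DDI classifier (", x$pooling, " pooling)\n", sep = "")
  cat("  trainable parameters:", format(x$n_parameters, big.mark = ","),
      "  pooled feature length:", x$pooled_dim, "\n")
  cat("  trained on", x$n_train, "instances\n")
  cat("  softmax column norms:",
      paste(sprintf("%.3f", x$ws_col_norms), collapse = " "), "\n")
  if (nrow(x$trace)) {
    cat("  training loss by epoch:\n")
    print(x$trace, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.ddi_cnn <- function(object, ...) object$params

#' @export
plot.ddi_cnn <- function(x, ...) {
  plot(c(0, x$trace$epoch), c(x$initial_loss, x$trace$loss), type = "b",
       xlab = "epoch", ylab = "mean training NLL",
       main = paste0("ddi_cnn (", x$pooling, " pooling)"), ...)
  graphics::abline(h = log(5), lty = 2, col = "grey50")
  invisible(x)
}

#' Predict DDI classes for new sentences
#'
#' Runs the fitted network (no dropout) over candidate-pair instances.
#' When `newdata` is a corpus it is prepared with the model's filter rules;
#' instances removed by the negative filter are scored as predicted
#' `"none"` (with a degenerate probability of 1 on `none`), so evaluation
#' against gold labels accounts for mistakenly filtered positives.
#'
#' @param object A fitted `ddi_cnn`.
#' @param newdata A `ddi_corpus`, a `ddi_dataset`, or a list of
#'   `ddi_instance`.
#' @param type `"response"` returns the full per-instance data frame;
#'   `"class"` just the predicted label vector.
#' @param ... Unused.
#' @return A data frame with `sentence_id`, `pair_id`, `gold`, `predicted`,
#'   `filtered`, and `score_<class>` probability columns (rows in input
#'   order), or a character vector for `type = "class"`.
#' @export
predict.ddi_cnn <- function(object, newdata,
                            type = c("response", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "ddi_corpus"))
    newdata <- ddi_prepare(newdata, object$rules)
  instances <- if (inherits(newdata, "ddi_dataset")) newdata$instances
               else newdata
  rows <- lapply(instances, function(inst) {
    scores <- rep(0, length(DDI_CLASSES))
    names(scores) <- DDI_CLASSES
    if (inst$filtered != "none") {
      scores["none"] <- 1
      pred <- "none"
    } else {
      enc <- ddi_encode(inst, object$vocab, object$config)
      if (is.null(enc)) {
        scores["none"] <- 1
        pred <- "none"
      } else {
        fw <- cnn_forward(enc, object$params, object$model_config, NULL)
        scores[] <- fw$probs
        pred <- DDI_CLASSES[which.max(fw$probs)]
      }
    }
    c(list(sentence_id = inst$sentence_id, pair_id = inst$pair_id,
           gold = inst$label, predicted = pred, filtered = inst$filtered),
      as.list(scores))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  names(out)[6:10] <- paste0("score_", DDI_CLASSES)
  if (type == "class") out$predicted else out
}
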