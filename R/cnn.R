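# The network core: embedding lookup, multi-width convolution with
# zero-fill stacking, the pooling operators (max, average, attentive, and
# the max+attentive combination), dropout and the softmax scorer -- plus the
# analytic backward pass for all of them. Everything is plain matrix code;
# gradients are verified against central finite differences in the test
# suite.

# ---- model configuration ---------------------------------------------------

# internal: full architecture description (encoder dims + conv/pooling)
model_config <- function(config, widths = c(2L, 4L, 6L), n_filters = 200L,
                         pooling = "max", attention_scope = "block",
                         pool_rows = "all", dropout = 0.5) {
  stopifnot(inherits(config, "ddi_encoder_config"))
  pooling <- match.arg(pooling, c("max", "avg", "attentive", "combined"))
  attention_scope <- match.arg(attention_scope, c("block", "stacked"))
  pool_rows <- match.arg(pool_rows, c("all", "valid"))
  widths <- sort(as.integer(widths))
  if (any(widths > config$n)) stop("filter width exceeds sentence length n")
  structure(list(n = config$n, m_e = config$m_e, m_d = config$m_d,
                 D = config$m_e + 2L * config$m_d,
                 widths = widths, m = as.integer(n_filters),
                 k = length(widths), pooling = pooling,
                 attention_scope = attention_scope, pool_rows = pool_rows,
                 dropout = dropout),
            class = "ddi_model_config")
}

att_dim <- function(cfg) if (cfg$attention_scope == "block")
  cfg$m * cfg$k else cfg$m

pooled_dim <- function(cfg) switch(cfg$pooling,
  max = , avg = cfg$m * cfg$k,
  attentive = att_dim(cfg),
  combined = cfg$m * cfg$k + att_dim(cfg))

# ---- parameters ------------------------------------------------------------

# Initialise all trainable tensors. Embedding tables are uniform(-.25,.25);
# filter banks use a fan-balanced uniform range; softmax weights and all
# biases start at zero so the untrained classifier is exactly uniform
# (initial loss log 5). Uses the caller's RNG stream.
ddi_params_init <- function(vocab_size, cfg) {
  D <- cfg$D
  u <- function(nr, nc, lim) matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  filters <- function() {
    fb <- lapply(cfg$widths, function(w) {
      lim <- sqrt(6 / (w * D + cfg$m))
      list(W = u(w * D, cfg$m, lim), b = numeric(cfg$m))
    })
    names(fb) <- as.character(cfg$widths)
    fb
  }
  n_branches <- if (cfg$pooling == "combined") 2L else 1L
  params <- list(
    W_e = u(vocab_size, cfg$m_e, 0.25),
    W_d1 = u(2L * cfg$n, cfg$m_d, 0.25),  # row = position code + 1; row 1 = pad
    W_d2 = u(2L * cfg$n, cfg$m_d, 0.25),
    F = lapply(seq_len(n_branches), function(b) filters()))
  if (cfg$pooling %in% c("attentive", "combined")) {
    lim <- sqrt(6 / (cfg$m + 1))
    params$w_alpha <- if (cfg$attention_scope == "block") {
      wa <- lapply(cfg$widths, function(w) stats::runif(cfg$m, -lim, lim))
      names(wa) <- as.character(cfg$widths)
      wa
    } else list(stacked = stats::runif(cfg$m, -lim, lim))
  }
  params$W_s <- matrix(0, pooled_dim(cfg), length(DDI_CLASSES))
  params$d <- numeric(length(DDI_CLASSES))
  params
}

# ---- word table layer ------------------------------------------------------

#' Embed an encoded instance
#'
#' Row `i` of the result concatenates the word embedding of token `i` with
#' the two position embeddings of its regrouped distances to the targets:
#' an `n x (m_e + 2 m_d)` input matrix.
#'
#' @param enc A [ddi_encode()] result.
#' @param W_e,W_d1,W_d2 Embedding tables: `|V| x m_e` words and
#'   `2n x m_d` positions (row = position code + 1; row 1 is the pad code).
#' @return Numeric matrix `n x (m_e + 2 m_d)`.
#' @export
ddi_embed <- function(enc, W_e, W_d1, W_d2) {
  cbind(W_e[enc$word_ids, , drop = FALSE],
        W_d1[enc$pos1_ids + 1L, , drop = FALSE],
        W_d2[enc$pos2_ids + 1L, , drop = FALSE])
}

# ---- convolutional layer ---------------------------------------------------

# windows matrix: row i = concatenated rows i..i+w-1 of X  ((n-w+1) x (w*D))
conv_windows <- function(X, w) {
  n <- nrow(X); D <- ncol(X); L <- n - w + 1L
  Xw <- matrix(0, L, w * D)
  for (j in seq_len(w))
    Xw[, ((j - 1L) * D + 1L):(j * D)] <- X[j:(j + L - 1L), , drop = FALSE]
  Xw
}

#' Convolve an input matrix with a filter bank of one window size
#'
#' Computes the score sequence `s_i = ReLU(sum_j <f_j, x_{i+j-1}> + b)` for
#' each of the `m` filters, `i = 1 .. n-w+1` (windows start at token `i`).
#'
#' @param X Input matrix `n x D` from [ddi_embed()].
#' @param W Filter bank `(w*D) x m` (each column one filter, rows grouped
#'   by window offset).
#' @param b Bias vector of length `m` (one per filter).
#' @return Score matrix `(n-w+1) x m` after the ReLU non-linearity.
#' @export
ddi_convolve <- function(X, W, b) {
  w <- nrow(W) / ncol(X)
  stopifnot(w == round(w), w <= nrow(X))
  A <- sweep(conv_windows(X, as.integer(w)) %*% W, 2L, b, "+")
  pmax(A, 0)
}

#' Stacked multi-width convolution output
#'
#' Applies one filter bank per window size and stacks the per-size score
#' blocks, each zero-filled to `n` rows, into the feature matrix the
#' pooling layer consumes.
#'
#' @param X Input matrix `n x D`.
#' @param filters Named list (by window size) of `list(W, b)` filter banks.
#' @return Object of class `ddi_fm`: list with `blocks` (per-size ReLU
#'   score matrices, `(n-w+1) x m` each), `widths`, `valid` (rows computed
#'   per block), `n` and `m`. Use [ddi_fm_matrix()] for the stacked
#'   `(n*k) x m` zero-filled form.
#' @export
ddi_feature_matrix <- function(X, filters) {
  n <- nrow(X)
  widths <- as.integer(names(filters))
  blocks <- lapply(filters, function(f) ddi_convolve(X, f$W, f$b))
  structure(list(blocks = blocks, widths = widths,
                 valid = n - widths + 1L, n = n,
                 m = ncol(blocks[[1]])),
            class = "ddi_fm")
}

#' @rdname ddi_feature_matrix
#' @param fm A `ddi_fm` object.
#' @export
ddi_fm_matrix <- function(fm) {
  do.call(rbind, lapply(fm$blocks, function(H)
    rbind(H, matrix(0, fm$n - nrow(H), ncol(H)))))
}

# per-block row count used by the pooling operators
pool_nrow <- function(fm, rows) if (rows == "all")
  rep(fm$n, length(fm$blocks)) else fm$valid

# block as pooled: zero-filled to n rows when rows = "all"
pool_block <- function(fm, i, rows) {
  H <- fm$blocks[[i]]
  if (rows == "all" && nrow(H) < fm$n)
    H <- rbind(H, matrix(0, fm$n - nrow(H), ncol(H)))
  H
}

# ---- pooling layer ---------------------------------------------------------

#' Pooling operators
#'
#' Reduce the stacked convolution output to the fixed-length feature vector
#' `z` the classifier consumes. `ddi_pool_max()` takes the per-filter
#' maximum, `ddi_pool_avg()` the per-filter mean, and
#' `ddi_pool_attentive()` a softmax-weighted combination
#' (`M = tanh(S)`, `alpha = softmax(M w_alpha)`, `z = tanh(alpha' S)`).
#' `ddi_pool_combined()` concatenates the max-pooled output of one filter
#' bank with the attentively pooled output of another.
#'
#' With `rows = "all"` (the default) pooling runs over all `n` rows of each
#' zero-filled block, matching the stacked feature-matrix shape;
#' `rows = "valid"` restricts to the `n-w+1` rows the convolution actually
#' computed. With `scope = "block"` attention is applied independently per
#' window-size block (one weight vector per block, outputs concatenated,
#' length `m*k`); with `scope = "stacked"` a single attention runs over the
#' full stacked matrix and the output has length `m`.
#'
#' @param fm,fm_a,fm_b [ddi_feature_matrix()] objects (`fm_a` feeds the max
#'   branch, `fm_b` the attentive branch).
#' @param w_alpha Attention weights: a list of `m`-vectors named by window
#'   size (`scope = "block"`), or a single `m`-vector
#'   (`scope = "stacked"`).
#' @param rows `"all"` or `"valid"`.
#' @param scope `"block"` or `"stacked"`.
#' @return Numeric feature vector `z` (block-major); for
#'   `ddi_pool_attentive` the attention weights are attached as attribute
#'   `"alpha"` (a list per block, each summing to 1).
#' @export
ddi_pool_max <- function(fm, rows = c("all", "valid")) {
  rows <- match.arg(rows)
  unlist(lapply(seq_along(fm$blocks), function(i)
    apply(pool_block(fm, i, rows), 2L, max)), use.names = FALSE)
}

#' @rdname ddi_pool_max
#' @export
ddi_pool_avg <- function(fm, rows = c("all", "valid")) {
  rows <- match.arg(rows)
  unlist(lapply(seq_along(fm$blocks), function(i)
    colMeans(pool_block(fm, i, rows))), use.names = FALSE)
}

#' @rdname ddi_pool_max
#' @export
ddi_pool_attentive <- function(fm, w_alpha, rows = c("all", "valid"),
                               scope = c("block", "stacked")) {
  rows <- match.arg(rows)
  scope <- match.arg(scope)
  fw <- attentive_forward(fm, w_alpha, rows, scope)
  structure(fw$z, alpha = lapply(fw$caches, `[[`, "alpha"))
}

#' @rdname ddi_pool_max
#' @export
ddi_pool_combined <- function(fm_a, fm_b, w_alpha, rows = c("all", "valid"),
                              scope = c("block", "stacked")) {
  rows <- match.arg(rows)
  scope <- match.arg(scope)
  c(ddi_pool_max(fm_a, rows),
    as.numeric(ddi_pool_attentive(fm_b, w_alpha, rows, scope)))
}

# attentive pooling with cached intermediates, one cache per attention unit
attentive_forward <- function(fm, w_alpha, rows, scope) {
  units <- if (scope == "block") {
    lapply(seq_along(fm$blocks), function(i)
      list(S = pool_block(fm, i, rows), wa = w_alpha[[i]]))
  } else {
    list(list(S = do.call(rbind, lapply(seq_along(fm$blocks), pool_block,
                                        fm = fm, rows = rows)),
              wa = if (is.list(w_alpha)) w_alpha[[1]] else w_alpha))
  }
  caches <- lapply(units, function(u) {
    M <- tanh(u$S)
    a <- drop(M %*% u$wa)
    alpha <- softmax_vec(a)
    t_ <- drop(crossprod(u$S, alpha))
    list(S = u$S, M = M, alpha = alpha, t = t_, z = tanh(t_), wa = u$wa)
  })
  list(z = unlist(lapply(caches, `[[`, "z"), use.names = FALSE),
       caches = caches)
}

# backward through one attention unit: given dz, return list(dS, dwa)
attentive_backward <- function(cache, dz) {
  dt <- dz * (1 - cache$z^2)
  dS <- outer(cache$alpha, dt)            # z = tanh(S' alpha) path
  dalpha <- drop(cache$S %*% dt)
  da <- cache$alpha * (dalpha - sum(cache$alpha * dalpha))  # softmax jac
  dwa <- drop(crossprod(cache$M, da))
  dS <- dS + outer(da, cache$wa) * (1 - cache$M^2)          # through tanh(S)
  list(dS = dS, dwa = dwa)
}

# numerically stable softmax of a vector
softmax_vec <- function(o) {
  e <- exp(o - max(o))
  e / sum(e)
}

# ---- softmax layer ---------------------------------------------------------

#' Score a pooled feature vector into class probabilities
#'
#' `o = z_d W_s + d` followed by a softmax over the five classes. During
#' training a Bernoulli dropout mask thins `z` (inverted dropout: kept
#' entries are scaled by `1/(1-p)` so inference needs no correction); at
#' test time no mask is applied.
#'
#' @param z Pooled feature vector.
#' @param W_s Softmax weights, `length(z) x 5`.
#' @param d Bias vector of length 5.
#' @param dropout_mask Optional 0/1 vector the length of `z` (training
#'   mode), or `NULL` for inference.
#' @param p Dropout probability the mask was drawn with.
#' @return Named probability vector over [DDI_CLASSES]; positive, sums
#'   to 1. The prediction is the arg-max, ties broken by the lowest class
#'   index.
#' @export
ddi_classify <- function(z, W_s, d, dropout_mask = NULL, p = 0.5) {
  zd <- if (is.null(dropout_mask)) z else z * dropout_mask / (1 - p)
  o <- drop(crossprod(W_s, zd)) + d
  pr <- softmax_vec(o)
  names(pr) <- DDI_CLASSES
  pr
}

# ---- full forward / backward ----------------------------------------------

# forward pass for one encoded instance; caches everything backward needs
cnn_forward <- function(enc, params, cfg, dropout_mask = NULL) {
  X <- ddi_embed(enc, params$W_e, params$W_d1, params$W_d2)
  Xw <- lapply(cfg$widths, function(w) conv_windows(X, w))
  names(Xw) <- as.character(cfg$widths)
  branches <- lapply(params$F, function(fb) {
    out <- lapply(as.character(cfg$widths), function(wn) {
      A <- sweep(Xw[[wn]] %*% fb[[wn]]$W, 2L, fb[[wn]]$b, "+")
      list(A = A, H = pmax(A, 0))
    })
    names(out) <- as.character(cfg$widths)
    out
  })
  fms <- lapply(branches, function(br)
    structure(list(blocks = lapply(br, `[[`, "H"), widths = cfg$widths,
                   valid = cfg$n - cfg$widths + 1L, n = cfg$n, m = cfg$m),
              class = "ddi_fm"))
  att <- NULL
  z <- switch(cfg$pooling,
    max = ddi_pool_max(fms[[1]], cfg$pool_rows),
    avg = ddi_pool_avg(fms[[1]], cfg$pool_rows),
    attentive = {
      att <- attentive_forward(fms[[1]], params$w_alpha, cfg$pool_rows,
                               cfg$attention_scope)
      att$z
    },
    combined = {
      att <- attentive_forward(fms[[2]], params$w_alpha, cfg$pool_rows,
                               cfg$attention_scope)
      c(ddi_pool_max(fms[[1]], cfg$pool_rows), att$z)
    })
  zd <- if (is.null(dropout_mask)) z else
    z * dropout_mask / (1 - cfg$dropout)
  o <- drop(crossprod(params$W_s, zd)) + params$d
  probs <- softmax_vec(o)
  list(X = X, Xw = Xw, branches = branches, fms = fms, att = att,
       z = z, zd = zd, mask = dropout_mask, o = o, probs = probs)
}

# backward pass: do = gradient of the loss w.r.t. the logits o.
# Returns a gradient tree with the same shape as params.
cnn_backward <- function(fw, enc, params, cfg, do) {
  g <- list()
  g$W_s <- outer(fw$zd, do)
  g$d <- do
  dzd <- drop(params$W_s %*% do)
  dz <- if (is.null(fw$mask)) dzd else
    dzd * fw$mask / (1 - cfg$dropout)

  mk <- cfg$m * cfg$k
  # per-branch gradient of the pooled vector w.r.t. each block's H
  dH <- lapply(seq_along(params$F), function(b)
    lapply(fw$branches[[b]], function(x) array(0, dim(x$H))))
  if (cfg$pooling %in% c("attentive", "combined"))
    g$w_alpha <- lapply(params$w_alpha, function(wa) numeric(length(wa)))

  add_block_grad <- function(branch, dSblocks) {
    # dSblocks: list per width of gradients on the (possibly zero-filled)
    # pooled block; rows beyond the valid length are structural zeros
    for (i in seq_along(dSblocks)) {
      L <- nrow(fw$branches[[branch]][[i]]$H)
      dH[[branch]][[i]] <<- dH[[branch]][[i]] +
        dSblocks[[i]][seq_len(L), , drop = FALSE]
    }
  }

  pool_backward_max <- function(branch, dzb) {
    # dzb: m*k gradient, block-major
    dSb <- vector("list", cfg$k)
    for (i in seq_len(cfg$k)) {
      H <- fw$branches[[branch]][[i]]$H
      dzi <- dzb[((i - 1L) * cfg$m + 1L):(i * cfg$m)]
      dS <- array(0, dim(H))
      amax <- max.col(t(H), ties.method = "first")
      dS[cbind(amax, seq_len(cfg$m))] <- dzi
      # rows = "all": if the true max were a zero-fill row the gradient
      # would vanish; H >= 0 so the per-column max over H already equals
      # the max over the zero-filled block and the ReLU derivative kills
      # the gradient when that max is 0.
      dSb[[i]] <- dS
    }
    add_block_grad(branch, dSb)
  }

  pool_backward_avg <- function(branch, dzb) {
    denom <- pool_nrow(fw$fms[[branch]], cfg$pool_rows)
    dSb <- vector("list", cfg$k)
    for (i in seq_len(cfg$k)) {
      H <- fw$branches[[branch]][[i]]$H
      dzi <- dzb[((i - 1L) * cfg$m + 1L):(i * cfg$m)]
      dSb[[i]] <- matrix(dzi / denom[i], nrow(H), cfg$m, byrow = TRUE)
    }
    add_block_grad(branch, dSb)
  }

  pool_backward_att <- function(branch, dzb) {
    caches <- fw$att$caches
    if (cfg$attention_scope == "block") {
      dSb <- vector("list", cfg$k)
      for (i in seq_len(cfg$k)) {
        bw <- attentive_backward(caches[[i]],
                                 dzb[((i - 1L) * cfg$m + 1L):(i * cfg$m)])
        dSb[[i]] <- bw$dS
        g$w_alpha[[i]] <<- g$w_alpha[[i]] + bw$dwa
      }
      add_block_grad(branch, dSb)
    } else {
      bw <- attentive_backward(caches[[1]], dzb)
      g$w_alpha[[1]] <<- g$w_alpha[[1]] + bw$dwa
      # split stacked rows back into per-width blocks
      rows_per <- pool_nrow(fw$fms[[branch]], cfg$pool_rows)
      off <- 0L
      dSb <- vector("list", cfg$k)
      for (i in seq_len(cfg$k)) {
        dSb[[i]] <- bw$dS[(off + 1L):(off + rows_per[i]), , drop = FALSE]
        off <- off + rows_per[i]
      }
      add_block_grad(branch, dSb)
    }
  }

  switch(cfg$pooling,
    max = pool_backward_max(1L, dz),
    avg = pool_backward_avg(1L, dz),
    attentive = pool_backward_att(1L, dz),
    combined = {
      pool_backward_max(1L, dz[seq_len(mk)])
      pool_backward_att(2L, dz[(mk + 1L):length(dz)])
    })

  # through ReLU, filters, and back to the input matrix
  D <- cfg$D
  dX <- array(0, dim(fw$X))
  g$F <- vector("list", length(params$F))
  for (b in seq_along(params$F)) {
    g$F[[b]] <- list()
    for (wn in as.character(cfg$widths)) {
      A <- fw$branches[[b]][[wn]]$A
      dA <- dH[[b]][[wn]] * (A > 0)
      W <- params$F[[b]][[wn]]$W
      g$F[[b]][[wn]] <- list(W = crossprod(fw$Xw[[wn]], dA),
                             b = colSums(dA))
      dXw <- dA %*% t(W)
      w <- as.integer(wn)
      L <- nrow(dA)
      for (j in seq_len(w)) {
        rows <- j:(j + L - 1L)
        dX[rows, ] <- dX[rows, ] +
          dXw[, ((j - 1L) * D + 1L):(j * D), drop = FALSE]
      }
    }
  }

  # scatter the input gradient into the three embedding tables
  g$W_e <- array(0, dim(params$W_e))
  g$W_d1 <- array(0, dim(params$W_d1))
  g$W_d2 <- array(0, dim(params$W_d2))
  acc <- function(tab, ids, dpart) {
    s <- rowsum(dpart, group = ids)
    tab[as.integer(rownames(s)), ] <- tab[as.integer(rownames(s)), ,
                                          drop = FALSE] + s
    tab
  }
  g$W_e <- acc(g$W_e, enc$word_ids, dX[, 1:cfg$m_e, drop = FALSE])
  g$W_d1 <- acc(g$W_d1, enc$pos1_ids + 1L,
                dX[, (cfg$m_e + 1L):(cfg$m_e + cfg$m_d), drop = FALSE])
  g$W_d2 <- acc(g$W_d2, enc$pos2_ids + 1L,
                dX[, (cfg$m_e + cfg$m_d + 1L):cfg$D, drop = FALSE])
  # order the tree like params so tree arithmetic lines up
  g[names(params)]
}
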