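# Forward and backward passes of the compact transformer encoder.
#
# Everything is plain double matrices (sequence length x hidden) so the
# matrix products run through BLAS; the backward pass is hand-derived for
# the fixed architecture (post-LN residual blocks, GELU feed-forward,
# multi-head scaled dot-product attention) and is verified against finite
# differences in the test suite.

LN_EPS <- 1e-12

layer_norm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + LN_EPS)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, g, `*`) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

layer_norm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, `*`)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

# GELU via the standard sigmoid approximation x * sigmoid(1.702 x)
# (cheap elementwise exp; accurate to ~1e-2, which is immaterial here since
# the same function is used in forward and backward).
gelu_fwd <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  x * s
}
gelu_grad <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  s + 1.702 * x * s * (1 - s)
}

row_max <- function(s) s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]

row_softmax <- function(s) {
  e <- exp(s - row_max(s))
  e / rowSums(e)
}

add_bias <- function(x, b) x + rep(b, each = nrow(x))

drop_mask <- function(n, m, p) {
  matrix(stats::rbinom(n * m, 1, 1 - p) / (1 - p), n, m)
}

# `train = TRUE` enables dropout (probability cfg$dropout, masks drawn from
# the current RNG stream and cached for the backward pass).
encoder_fwd <- function(model, ids, segment_ids, cache = FALSE,
                        train = FALSE) {
  p <- model$params
  cfg <- model$config
  n <- length(ids)
  dp <- if (train) cfg$dropout else 0
  x0 <- p$tok[ids + 1L, , drop = FALSE] +
    p$pos[seq_len(n), , drop = FALSE] +
    p$seg[segment_ids + 1L, , drop = FALSE]
  ln0 <- layer_norm_fwd(x0, p$ln_emb_g, p$ln_emb_b)
  e <- ln0$y
  m0 <- NULL
  if (dp > 0) {
    m0 <- drop_mask(n, cfg$hidden_dim, dp)
    e <- e * m0
  }
  nh <- cfg$num_heads
  dh <- cfg$hidden_dim %/% nh
  scale <- 1 / sqrt(dh)
  caches <- if (cache) vector("list", cfg$num_layers)
  for (l in seq_len(cfg$num_layers)) {
    w <- p$layers[[l]]
    q <- add_bias(e %*% w$Wq, w$bq)
    k <- add_bias(e %*% w$Wk, w$bk)
    v <- add_bias(e %*% w$Wv, w$bv)
    ctx <- matrix(0, n, cfg$hidden_dim)
    attn <- if (cache) vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      a <- row_softmax(tcrossprod(q[, cols, drop = FALSE],
                                  k[, cols, drop = FALSE]) * scale)
      ctx[, cols] <- a %*% v[, cols, drop = FALSE]
      if (cache) attn[[h]] <- a
    }
    o <- add_bias(ctx %*% w$Wo, w$bo)
    mo <- mf <- NULL
    if (dp > 0) {
      mo <- drop_mask(n, cfg$hidden_dim, dp)
      o <- o * mo
    }
    r1 <- e + o
    ln1 <- layer_norm_fwd(r1, w$ln1g, w$ln1b)
    hff <- add_bias(ln1$y %*% w$W1, w$b1)
    gff <- gelu_fwd(hff)
    f2 <- add_bias(gff %*% w$W2, w$b2)
    if (dp > 0) {
      mf <- drop_mask(n, cfg$hidden_dim, dp)
      f2 <- f2 * mf
    }
    r2 <- ln1$y + f2
    ln2 <- layer_norm_fwd(r2, w$ln2g, w$ln2b)
    if (cache) {
      caches[[l]] <- list(e_in = e, q = q, k = k, v = v, attn = attn,
                          ctx = ctx, ln1 = ln1, hff = hff, gff = gff,
                          mo = mo, mf = mf)
    }
    e <- ln2$y
    if (cache) caches[[l]]$ln2 <- ln2
  }
  if (cache) {
    list(out = e, ln0 = ln0, m0 = m0, layers = caches, ids = ids,
         segment_ids = segment_ids)
  } else {
    e
  }
}

# d_out: gradient of the loss wrt encoder output (n x H).
# Returns a gradient tree mirroring model$params (heads untouched = zeros
# are added by the caller as needed).
encoder_bwd <- function(model, fw, d_out) {
  p <- model$params
  cfg <- model$config
  nh <- cfg$num_heads
  dh <- cfg$hidden_dim %/% nh
  scale <- 1 / sqrt(dh)
  n <- nrow(d_out)
  g_layers <- vector("list", cfg$num_layers)
  de <- d_out
  for (l in rev(seq_len(cfg$num_layers))) {
    w <- p$layers[[l]]
    cc <- fw$layers[[l]]
    ln2b <- layer_norm_bwd(de, cc$ln2, w$ln2g)
    dr2 <- ln2b$dx
    df2 <- if (is.null(cc$mf)) dr2 else dr2 * cc$mf
    dgff <- df2 %*% t(w$W2)
    gW2 <- crossprod(cc$gff, df2)
    gb2 <- colSums(df2)
    dhff <- dgff * gelu_grad(cc$hff)
    gW1 <- crossprod(cc$ln1$y, dhff)
    gb1 <- colSums(dhff)
    dln1y <- dr2 + dhff %*% t(w$W1)
    ln1b <- layer_norm_bwd(dln1y, cc$ln1, w$ln1g)
    dr1 <- ln1b$dx
    do_ <- if (is.null(cc$mo)) dr1 else dr1 * cc$mo
    dctx <- do_ %*% t(w$Wo)
    gWo <- crossprod(cc$ctx, do_)
    gbo <- colSums(do_)
    dq <- matrix(0, n, cfg$hidden_dim)
    dk <- matrix(0, n, cfg$hidden_dim)
    dv <- matrix(0, n, cfg$hidden_dim)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      a <- cc$attn[[h]]
      dch <- dctx[, cols, drop = FALSE]
      da <- tcrossprod(dch, cc$v[, cols, drop = FALSE])
      dv[, cols] <- crossprod(a, dch)
      ds <- a * (da - rowSums(da * a))
      dq[, cols] <- ds %*% cc$k[, cols, drop = FALSE] * scale
      dk[, cols] <- crossprod(ds, cc$q[, cols, drop = FALSE]) * scale
    }
    gWq <- crossprod(cc$e_in, dq)
    gWk <- crossprod(cc$e_in, dk)
    gWv <- crossprod(cc$e_in, dv)
    de <- dr1 + dq %*% t(w$Wq) + dk %*% t(w$Wk) + dv %*% t(w$Wv)
    g_layers[[l]] <- list(Wq = gWq, bq = colSums(dq),
                          Wk = gWk, bk = colSums(dk),
                          Wv = gWv, bv = colSums(dv),
                          Wo = gWo, bo = gbo,
                          ln1g = ln1b$dg, ln1b = ln1b$db,
                          W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                          ln2g = ln2b$dg, ln2b = ln2b$db)
  }
  if (!is.null(fw$m0)) de <- de * fw$m0
  ln0b <- layer_norm_bwd(de, fw$ln0, p$ln_emb_g)
  dx0 <- ln0b$dx
  gtok <- matrix(0, cfg$vocab_size, cfg$hidden_dim)
  acc <- rowsum(dx0, fw$ids)
  gtok[as.integer(rownames(acc)) + 1L, ] <- acc
  gpos <- matrix(0, cfg$max_position, cfg$hidden_dim)
  gpos[seq_len(n), ] <- dx0
  gseg <- rowsum(dx0, fw$segment_ids)
  gseg_full <- matrix(0, 2, cfg$hidden_dim)
  gseg_full[as.integer(rownames(gseg)) + 1L, ] <- gseg
  list(tok = gtok, pos = gpos, seg = gseg_full,
       ln_emb_g = ln0b$dg, ln_emb_b = ln0b$db,
       layers = g_layers)
}

zero_head_grads <- function(model) {
  p <- model$params
  g <- list(mlm_W = p$mlm_W * 0, mlm_b = p$mlm_b * 0,
            span_W = p$span_W * 0, span_b = p$span_b * 0)
  if (!is.null(p$cls_W)) {
    g$cls_W <- p$cls_W * 0
    g$cls_b <- p$cls_b * 0
  }
  g
}

validate_encoding_for_model <- function(model, encoding) {
  cfg <- model$config
  bad <- which(encoding$ids < 0 | encoding$ids >= cfg$vocab_size)
  if (length(bad) > 0) {
    stop(sprintf("token id %d at position %d is out of range [0, %d)",
                 encoding$ids[bad[1]], bad[1], cfg$vocab_size))
  }
  if (length(encoding$ids) > cfg$max_position) {
    stop(sprintf("encoding length %d exceeds max_position %d",
                 length(encoding$ids), cfg$max_position))
  }
  invisible(TRUE)
}

#' Contextual encoder forward pass (evaluation mode)
#'
#' @param model a `pb_model`.
#' @param encoding a `wp_encoding` whose ids fit the model's vocabulary and
#'   whose length does not exceed `max_position`.
#' @return a numeric matrix (encoding length x hidden_dim); deterministic.
#' @export
forward_encode <- function(model, encoding) {
  stopifnot(inherits(model, "pb_model"), inherits(encoding, "wp_encoding"))
  validate_encoding_for_model(model, encoding)
  encoder_fwd(model, encoding$ids, encoding$segment_ids, cache = FALSE)
}

#' Numerically stable softmax over a score vector
#'
#' Computes `exp(s_i) / sum_j exp(s_j)` shift-invariantly (the maximum is
#' subtracted first), so e.g. scores `c(1000, 0)` do not overflow.
#'
#' @param scores finite numeric vector.
#' @return probability vector summing to 1.
#' @export
softmax_probs <- function(scores) {
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("softmax_probs requires finite scores")
  }
  e <- exp(scores - max(scores))
  e / sum(e)
}

log_softmax_rows <- function(s) {
  sc <- s - row_max(s)
  sc - log(rowSums(exp(sc)))
}

#' Cross-entropy loss
#'
#' Returns `-log p[truth]` for a single probability vector, or the mean of
#' the per-row losses when `probs` is a matrix and `truth` a vector of class
#' indices (1-based). Probabilities below `1e-12` are floored (with a
#' message) so the loss stays finite.
#'
#' @param probs probability vector, or matrix with one distribution per row.
#' @param truth 1-based true class index (vector for the batch version).
#' @return non-negative real.
#' @export
cross_entropy_loss <- function(probs, truth) {
  if (is.matrix(probs)) {
    stopifnot(length(truth) == nrow(probs))
    p <- probs[cbind(seq_len(nrow(probs)), truth)]
  } else {
    if (truth < 1 || truth > length(probs)) {
      stop("truth index out of range")
    }
    p <- probs[truth]
  }
  if (any(p < 1e-12)) {
    message("cross_entropy_loss: probability floored at 1e-12")
    p <- pmax(p, 1e-12)
  }
  mean(-log(p))
}

#' Span start/end scores for an encoding
#'
#' One shared linear map over the contextual vectors produces two scores per
#' position: the start score vector S and end score vector E.
#'
#' @inheritParams forward_encode
#' @return list with numeric vectors `S` and `E`, each of encoding length.
#' @export
span_logits <- function(model, encoding) {
  hidden <- forward_encode(model, encoding)
  z <- add_bias(hidden %*% model$params$span_W, model$params$span_b)
  list(S = z[, 1], E = z[, 2])
}

#' Per-position vocabulary scores (masked-token prediction head)
#'
#' @inheritParams forward_encode
#' @return numeric matrix (encoding length x vocab_size).
#' @export
mlm_logits <- function(model, encoding) {
  hidden <- forward_encode(model, encoding)
  add_bias(hidden %*% model$params$mlm_W, model$params$mlm_b)
}

#' Class scores from the `[CLS]` position
#'
#' Reads only the contextual vector at position 1 (which must hold `[CLS]`).
#' The classifier head is created on first use with `num_classes` outputs
#' (seeded from the model config).
#'
#' @inheritParams forward_encode
#' @param num_classes number of classes (>= 2).
#' @return numeric vector of `num_classes` scores.
#' @export
cls_logits <- function(model, encoding, num_classes) {
  if (num_classes < 2) stop("num_classes must be at least 2")
  if (encoding$tokens[1] != "[CLS]") {
    stop("position 1 of the encoding must hold [CLS]")
  }
  model <- ensure_cls_head(model, num_classes)
  hidden <- forward_encode(model, encoding)
  drop(hidden[1, , drop = FALSE] %*% model$params$cls_W + model$params$cls_b)
}

ensure_cls_head <- function(model, num_classes) {
  if (!is.null(model$params$cls_W)) {
    if (ncol(model$params$cls_W) != num_classes) {
      stop(sprintf("classifier head has %d classes, requested %d",
                   ncol(model$params$cls_W), num_classes))
    }
    return(model)
  }
  H <- model$config$hidden_dim
  model$params$cls_W <- with_preserved_rng({
    set.seed(model$config$seed + 7919L)
    rmat(H, num_classes, model$config$init_std)
  })
  model$params$cls_b <- numeric(num_classes)
  model
}
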