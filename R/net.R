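# Non-linear genomic predictor: a locally connected network. The first layer
# partitions the one-hot genotype columns into contiguous windows of variants,
# each window feeding its own private hidden units (no weight sharing across
# windows); covariates join at the first dense layer. Trained with Adam on
# mean squared error with early stopping on validation loss. Written in plain
# matrix algebra so input gradients (for integrated gradients) are exact.

relu <- function(x) x * (x > 0)

# block-diagonal 0/1 mask: p_geno columns -> n_windows * units_per_window units
lc_mask <- function(n_variants, cols_per_variant = 4L, window = 4L,
                    units_per_window = 4L) {
  n_win <- ceiling(n_variants / window)
  p <- n_variants * cols_per_variant
  M <- matrix(0, p, n_win * units_per_window)
  for (w in seq_len(n_win)) {
    v0 <- (w - 1L) * window + 1L
    v1 <- min(w * window, n_variants)
    rows <- ((v0 - 1L) * cols_per_variant + 1L):(v1 * cols_per_variant)
    cols <- ((w - 1L) * units_per_window + 1L):(w * units_per_window)
    M[rows, cols] <- 1
  }
  M
}

lc_net_init <- function(p_geno, p_cov, arch, seed) {
  set.seed(seed)
  mask <- lc_mask(arch$n_variants, arch$cols_per_variant, arch$window,
                  arch$units_per_window)
  h1 <- ncol(mask)
  d_in <- h1 + p_cov
  he <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  # fan-in of a locally connected unit is its window width, not p_geno
  fan1 <- arch$window * arch$cols_per_variant
  layers <- list(W1 = matrix(rnorm(p_geno * h1, 0, sqrt(2 / fan1)),
                             p_geno, h1) * mask,
                 b1 = rep(0, h1))
  widths <- c(d_in, arch$hidden, 1L)
  for (l in seq_len(length(widths) - 1L)) {
    layers[[paste0("Wd", l)]] <- he(widths[l], widths[l + 1L])
    layers[[paste0("bd", l)]] <- rep(0, widths[l + 1L])
  }
  # zero-init output layer + linear residual shortcut input -> output:
  # training starts from the pure linear model, and the hidden path only
  # grows where linearity leaves residual signal
  layers[[paste0("Wd", length(widths) - 1L)]][] <- 0
  layers$Ws <- matrix(0, p_geno, 1)
  if (p_cov > 0) layers$Wc <- matrix(0, p_cov, 1)
  list(params = layers, mask = mask, arch = arch, p_geno = p_geno,
       p_cov = p_cov, n_dense = length(widths) - 1L,
       cov_center = rep(0, p_cov), cov_scale = rep(1, p_cov))
}

# forward pass; drop (list of dropout masks) only during training
lc_net_forward <- function(net, X_geno, X_cov = NULL, drop = NULL) {
  P <- net$params
  if (net$p_cov > 0) {
    X_cov <- sweep(sweep(as.matrix(X_cov), 2, net$cov_center), 2,
                   net$cov_scale, "/")
  }
  z1 <- X_geno %*% P$W1
  z1 <- sweep(z1, 2, P$b1, "+")
  a1 <- relu(z1)
  a <- if (net$p_cov > 0) cbind(a1, X_cov) else a1
  cache <- list(X_geno = X_geno, X_cov = X_cov, z1 = z1, acts = list(a))
  for (l in seq_len(net$n_dense)) {
    z <- sweep(a %*% P[[paste0("Wd", l)]], 2, P[[paste0("bd", l)]], "+")
    if (l < net$n_dense) {
      a <- relu(z)
      if (!is.null(drop)) a <- a * drop[[l]]
    } else {
      a <- z
    }
    cache$zs[[l]] <- z
    cache$acts[[l + 1L]] <- a
  }
  skip <- X_geno %*% P$Ws
  if (net$p_cov > 0) skip <- skip + X_cov %*% P$Wc
  list(yhat = as.vector(a) + as.vector(skip), cache = cache)
}

# gradients of 0.5 * mean((yhat - y)^2) wrt parameters, and wrt inputs
lc_net_backward <- function(net, cache, delta_out, drop = NULL,
                            want_input_grad = FALSE) {
  P <- net$params
  n <- length(delta_out)
  grads <- list()
  delta <- matrix(delta_out, n, 1)
  for (l in rev(seq_len(net$n_dense))) {
    a_prev <- cache$acts[[l]]
    grads[[paste0("Wd", l)]] <- crossprod(a_prev, delta)
    grads[[paste0("bd", l)]] <- colSums(delta)
    delta <- delta %*% t(P[[paste0("Wd", l)]])
    if (l > 1L) {
      act_grad <- (cache$zs[[l - 1L]] > 0)
      if (!is.null(drop)) act_grad <- act_grad * drop[[l - 1L]]
      delta <- delta * act_grad
    }
  }
  # delta now spans [a1 | covariates]
  h1 <- ncol(net$mask)
  delta1 <- delta[, seq_len(h1), drop = FALSE] * (cache$z1 > 0)
  grads$W1 <- crossprod(cache$X_geno, delta1) * net$mask
  grads$b1 <- colSums(delta1)
  grads$Ws <- crossprod(cache$X_geno, matrix(delta_out, n, 1))
  if (net$p_cov > 0) {
    grads$Wc <- crossprod(cache$X_cov, matrix(delta_out, n, 1))
  }
  out <- list(grads = grads)
  if (want_input_grad) {
    out$g_geno <- delta1 %*% t(P$W1) +
      matrix(delta_out, n, 1) %*% t(P$Ws)
    if (net$p_cov > 0) {
      g_cov <- delta[, (h1 + 1L):ncol(delta), drop = FALSE] +
        matrix(delta_out, n, 1) %*% t(P$Wc)
      out$g_cov <- sweep(g_cov, 2, net$cov_scale, "/")
    }
  }
  out
}

#' Fit the locally connected non-linear predictor
#'
#' @param design list with one-hot genotype matrices `train` and `val`
#'   (rows = samples; 4 columns per variant as produced by [encode()])
#' @param covariates optional list with numeric covariate matrices `train`
#'   and `val` (standardized internally on training statistics)
#' @param y_train,y_val trait values for the two splits
#' @param arch architecture overrides: `window` (variants per locally
#'   connected window, default 4), `units_per_window` (4), `hidden`
#'   (c(128, 128)), `dropout` (0.1), `lr` (1e-3), `batch_size` (128),
#'   `max_epochs` (150), `patience` (10 validation checks)
#' @param seed RNG seed (initialization, shuffling, dropout)
#' @return `model_bundle` of kind `"nonlinear_net"`; `$meta` records epochs
#'   run, best validation loss and validation R-squared
#' @export
fit_nonlinear_predictor <- function(design, covariates = NULL, y_train, y_val,
                                    arch = list(), seed = 1L) {
  Xg_tr <- as.matrix(design$train); Xg_va <- as.matrix(design$val)
  Xc_tr <- if (!is.null(covariates)) as.matrix(covariates$train) else NULL
  Xc_va <- if (!is.null(covariates)) as.matrix(covariates$val) else NULL
  a <- list(window = 4L, units_per_window = 4L, hidden = c(128L, 128L),
            dropout = 0.1, lr = 1e-3, weight_decay = 1e-3,
            batch_size = 128L, max_epochs = 150L,
            patience = 10L, cols_per_variant = 4L)
  a[names(arch)] <- arch
  assert_that(ncol(Xg_tr) %% a$cols_per_variant == 0,
              "genotype design width is not a multiple of cols_per_variant")
  a$n_variants <- ncol(Xg_tr) %/% a$cols_per_variant
  p_cov <- if (is.null(Xc_tr)) 0L else ncol(Xc_tr)
  net <- lc_net_init(ncol(Xg_tr), p_cov, a, seed)
  if (p_cov > 0) {
    net$cov_center <- colMeans(Xc_tr)
    sds <- apply(Xc_tr, 2, sd)
    net$cov_scale <- ifelse(sds > 0, sds, 1)
  }
  # Adam state
  mstate <- lapply(net$params, function(p) p * 0)
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0
  n <- nrow(Xg_tr)
  best <- list(loss = Inf, params = net$params, epoch = 0L)
  bad <- 0L
  val_loss <- function() {
    yh <- lc_net_forward(net, Xg_va, Xc_va)$yhat
    mean((yh - y_val)^2)
  }
  epochs_run <- 0L
  if (a$max_epochs > 0) for (epoch in seq_len(a$max_epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = a$batch_size)) {
      idx <- ord[start:min(start + a$batch_size - 1L, n)]
      drop <- NULL
      if (a$dropout > 0) {
        drop <- lapply(seq_len(net$n_dense - 1L), function(l) {
          w <- if (l == 1L) a$hidden[1] else a$hidden[l]
          matrix((runif(length(idx) * w) > a$dropout) / (1 - a$dropout),
                 length(idx), w)
        })
      }
      fw <- lc_net_forward(net, Xg_tr[idx, , drop = FALSE],
                           if (p_cov > 0) Xc_tr[idx, , drop = FALSE],
                           drop = drop)
      delta <- (fw$yhat - y_train[idx]) / length(idx)
      bw <- lc_net_backward(net, fw$cache, delta, drop = drop)
      t_step <- t_step + 1
      for (nm in names(net$params)) {
        g <- bw$grads[[nm]]
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g^2
        mhat <- mstate[[nm]] / (1 - b1^t_step)
        vhat <- vstate[[nm]] / (1 - b2^t_step)
        # decoupled (AdamW-style) weight decay on weights, not biases
        decay <- if (grepl("^W", nm)) a$lr * a$weight_decay else 0
        net$params[[nm]] <- net$params[[nm]] * (1 - decay) -
          a$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    vl <- val_loss()
    assert_that(is.finite(vl), "training diverged: non-finite validation loss")
    epochs_run <- epoch
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, params = net$params, epoch = epoch)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= a$patience) break
    }
  }
  net$params <- best$params
  yh_val <- lc_net_forward(net, Xg_va, Xc_va)$yhat
  structure(list(kind = "nonlinear_net", net = net, seed = seed,
                 p = ncol(Xg_tr) + p_cov,
                 meta = list(epochs = epochs_run, best_epoch = best$epoch,
                             val_loss = mean((yh_val - y_val)^2),
                             val_r2 = r2_score(y_val, yh_val))),
            class = "model_bundle")
}

#' Integrated-gradients attribution
#'
#' Straight-path integrated gradients with a midpoint Riemann sum:
#' `(x - x') * mean_k grad f(x' + (k - 0.5)/n_steps (x - x'))`. The default
#' baseline is the all-zero one-hot genotype vector with covariates at their
#' training means (zero in standardized units).
#'
#' @param model `model_bundle` of kind `"nonlinear_net"`
#' @param X_val list with `X_geno` (one-hot matrix) and optional `X_cov`
#' @param baseline optional list with `X_geno`/`X_cov` baseline rows (a single
#'   row, recycled); default as described
#' @param n_steps path resolution (>= 2)
#' @return list of class `attribution`: `attr_geno`, `attr_cov` (per-sample,
#'   per-column attributions), `completeness_err` (max abs deviation of the
#'   attribution sum from f(x) - f(baseline)), `n_steps`
#' @export
attribute_integrated_gradients <- function(model, X_val, baseline = NULL,
                                           n_steps = 64L) {
  assert_that(n_steps >= 2, "n_steps must be >= 2")
  assert_that(model$kind == "nonlinear_net", "model must be a nonlinear_net")
  net <- model$net
  Xg <- as.matrix(X_val$X_geno)
  Xc <- if (net$p_cov > 0) as.matrix(X_val$X_cov) else NULL
  n <- nrow(Xg)
  bg <- matrix(0, n, ncol(Xg))
  bc <- if (net$p_cov > 0)
    matrix(net$cov_center, n, net$p_cov, byrow = TRUE) else NULL
  if (!is.null(baseline)) {
    bg <- matrix(as.numeric(baseline$X_geno), n, ncol(Xg), byrow = TRUE)
    if (net$p_cov > 0)
      bc <- matrix(as.numeric(baseline$X_cov), n, net$p_cov, byrow = TRUE)
  }
  dg <- Xg - bg
  dc <- if (net$p_cov > 0) Xc - bc else NULL
  acc_g <- matrix(0, n, ncol(Xg))
  acc_c <- if (net$p_cov > 0) matrix(0, n, net$p_cov) else NULL
  for (k in seq_len(n_steps)) {
    t_k <- (k - 0.5) / n_steps
    fw <- lc_net_forward(net, bg + t_k * dg,
                         if (net$p_cov > 0) bc + t_k * dc)
    bwd <- lc_net_backward(net, fw$cache, rep(1, n), want_input_grad = TRUE)
    acc_g <- acc_g + bwd$g_geno
    if (net$p_cov > 0) acc_c <- acc_c + bwd$g_cov
  }
  attr_geno <- dg * acc_g / n_steps
  attr_cov <- if (net$p_cov > 0) dc * acc_c / n_steps else NULL
  f_x <- lc_net_forward(net, Xg, Xc)$yhat
  f_b <- lc_net_forward(net, bg, if (net$p_cov > 0) bc)$yhat
  total <- rowSums(attr_geno) + if (net$p_cov > 0) rowSums(attr_cov) else 0
  structure(list(attr_geno = attr_geno, attr_cov = attr_cov,
                 completeness_err = max(abs(total - (f_x - f_b))),
                 n_steps = n_steps),
            class = "attribution")
}

#' Per-variant attribution scores
#'
#' Mean over validation samples and the variant's one-hot columns of absolute
#' attributions.
#'
#' @param attribution result of [attribute_integrated_gradients()]
#' @param variant_ids variant ids in design column order
#' @param cols_per_variant one-hot columns per variant
#' @return named numeric vector of per-variant scores
#' @export
variant_attribution <- function(attribution, variant_ids,
                                cols_per_variant = 4L) {
  A <- abs(attribution$attr_geno)
  m <- length(variant_ids)
  assert_that(ncol(A) == m * cols_per_variant,
              "attribution width does not match variant count")
  grp <- rep(seq_len(m), each = cols_per_variant)
  setNames(as.vector(tapply(colMeans(A), grp, mean)), variant_ids)
}

#' Select the top attributed variants
#'
#' Scores are averaged (absolute values first) across runs; ties across the
#' k boundary are broken by ascending variant index.
#'
#' @param attr_by_run list of named per-variant score vectors, one per run,
#'   sharing the same variant order
#' @param k number of variants to keep (capped at the number available)
#' @return character vector of selected variant ids, highest score first
#' @export
select_top_snvs <- function(attr_by_run, k = 128L) {
  assert_that(length(attr_by_run) >= 1, "need at least one attribution run")
  scores <- rowMeans(vapply(attr_by_run, function(s) abs(as.numeric(s)),
                            numeric(length(attr_by_run[[1]]))))
  ids <- names(attr_by_run[[1]])
  if (k > length(scores)) {
    message(sprintf("k = %d exceeds %d variants; returning all", k,
                    length(scores)))
    k <- length(scores)
  }
  ord <- order(-scores, seq_along(scores))
  ids[ord[seq_len(k)]]
}
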