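# Low-level differentiable layers. Every layer exposes a *_fwd returning
# list(y, cache) and a *_bwd(cache, dy) returning gradients; the backward
# formulas are analytic and are validated against central finite differences
# in the test suite. Token grids are arrays [B, H, W, C] (column-major), so
# `dim(x) <- c(B*H*W, C)` yields the token-by-channel matrix directly.

grid_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[-length(d)]), d[length(d)])
  x
}

col_scale <- function(m, v) m * rep(v, each = nrow(m))

sigmoid <- function(x) 1 / (1 + exp(-x))
silu <- function(x) x * sigmoid(x)
dsilu <- function(x) { s <- sigmoid(x); s * (1 + x * (1 - s)) }
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))  # branch-free, stable

# truncated-normal init (sd 0.02, clipped at 2 sd), consumes the current RNG
tn_init <- function(nr, nc = NULL, sd = 0.02) {
  n <- if (is.null(nc)) nr else nr * nc
  v <- stats::rnorm(n, sd = sd)
  v <- pmin(pmax(v, -2 * sd), 2 * sd)
  if (is.null(nc)) v else matrix(v, nr, nc)
}

## ---- layer norm over the channel (last) dim ----

ln_fwd <- function(xm, g, b, eps = 1e-6) {
  C <- ncol(xm)
  mu <- rowMeans(xm)
  xc <- xm - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xh <- xc * inv
  y <- col_scale(xh, g) + rep(b, each = nrow(xm))
  list(y = y, cache = list(xh = xh, inv = inv, g = g, C = C))
}

ln_bwd <- function(cache, dy) {
  xh <- cache$xh; inv <- cache$inv; C <- cache$C
  dxh <- col_scale(dy, cache$g)
  r1 <- rowSums(dxh)
  r2 <- rowSums(dxh * xh)
  dx <- (inv / C) * (C * dxh - r1 - xh * r2)
  list(dx = dx, dg = colSums(dy * xh), db = colSums(dy))
}

## ---- patch embedding ----

init_patch_embed <- function(patch_h, patch_w, embed_dim) {
  list(W = tn_init(patch_h * patch_w, embed_dim), b = numeric(embed_dim))
}

patch_embed_fwd <- function(p, x, patch_h, patch_w) {
  d <- dim(x)  # [B, ch, samp]
  B <- d[1]
  gh <- ceiling(d[2] / patch_h); gw <- ceiling(d[3] / patch_w)
  chp <- gh * patch_h; spp <- gw * patch_w
  if (chp != d[2] || spp != d[3]) {
    xp <- array(0, dim = c(B, chp, spp))
    xp[, seq_len(d[2]), seq_len(d[3])] <- x
  } else xp <- x
  dim(xp) <- c(B, patch_h, gh, patch_w, gw)
  xp <- aperm(xp, c(1, 3, 5, 2, 4))          # [B, gh, gw, ph, pw]
  dim(xp) <- c(B * gh * gw, patch_h * patch_w)
  y <- xp %*% p$W + rep(p$b, each = B * gh * gw)
  dim(y) <- c(B, gh, gw, ncol(p$W))
  list(y = y, cache = list(xp = xp, B = B, gh = gh, gw = gw))
}

patch_embed_bwd <- function(p, cache, dy) {
  dim(dy) <- c(nrow(cache$xp), ncol(p$W))
  list(dW = crossprod(cache$xp, dy), db = colSums(dy))
}

## ---- 2x2 patch-merging downsample ----

init_downsample <- function(dim_in) {
  list(W = tn_init(4 * dim_in, 2 * dim_in), b = numeric(2 * dim_in))
}

downsample_fwd <- function(p, x) {
  d <- dim(x)  # [B, H, W, C]
  B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  Hh <- ceiling(H / 2); Wh <- ceiling(W / 2)
  if (2 * Hh != H || 2 * Wh != W) {
    xp <- array(0, dim = c(B, 2 * Hh, 2 * Wh, C))
    xp[, seq_len(H), seq_len(W), ] <- x
  } else xp <- x
  dim(xp) <- c(B, 2, Hh, 2, Wh, C)
  xp <- aperm(xp, c(1, 3, 5, 2, 4, 6))       # [B, Hh, Wh, 2, 2, C]
  dim(xp) <- c(B * Hh * Wh, 4 * C)
  y <- xp %*% p$W + rep(p$b, each = B * Hh * Wh)
  dim(y) <- c(B, Hh, Wh, 2 * C)
  list(y = y, cache = list(xp = xp, B = B, H = H, W = W, C = C, Hh = Hh, Wh = Wh))
}

downsample_bwd <- function(p, cache, dy) {
  ca <- cache
  dim(dy) <- c(nrow(ca$xp), 2 * ca$C)
  dxp <- tcrossprod(dy, p$W)
  dW <- crossprod(ca$xp, dy); db <- colSums(dy)
  dim(dxp) <- c(ca$B, ca$Hh, ca$Wh, 2, 2, ca$C)
  dxp <- aperm(dxp, c(1, 4, 2, 5, 3, 6))
  dim(dxp) <- c(ca$B, 2 * ca$Hh, 2 * ca$Wh, ca$C)
  dx <- dxp[, seq_len(ca$H), seq_len(ca$W), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

## ---- VSS block (SS2D and lite variants) ----

# four traversal orders of an H x W token grid over its natural
# (h-fastest, column-major) flattening
scan_orders <- function(H, W) {
  L <- H * W
  row_major <- as.vector(t(matrix(seq_len(L), H, W)))  # left->right, row by row
  list(row_major, rev(row_major), seq_len(L), rev(seq_len(L)))
}

init_vss_block <- function(C, state_dim, expansion, variant = "ss2d") {
  Di <- expansion * C
  N <- state_dim
  R <- max(1L, ceiling(Di / 8))
  p <- list(
    ln1_g = rep(1, C), ln1_b = numeric(C),
    Win = tn_init(C, 2 * Di), bin = numeric(2 * Di),
    Kconv = array(tn_init(9 * Di, sd = 0.1), dim = c(3, 3, Di)),
    bconv = numeric(Di),
    lnO_g = rep(1, Di), lnO_b = numeric(Di),
    # small random init: a zero output projection makes the whole network the
    # identity map, and at desk-scale widths escaping that plateau proved
    # unreliable; sd 0.02 keeps blocks near-identity but differentiable-useful
    Wout = tn_init(Di, C), bout = numeric(C))
  if (variant == "ss2d") {
    dirs <- vector("list", 4)
    for (k in 1:4) {
      dt0 <- exp(stats::runif(Di, log(1e-3), log(1e-1)))
      dirs[[k]] <- list(
        Wx = tn_init(Di, R + 2 * N),
        Wdt = tn_init(R, Di), bdt = log(expm1(dt0)),
        Alog = matrix(log(seq_len(N)), Di, N, byrow = TRUE),
        Dskip = rep(1, Di))
    }
    p$dirs <- dirs
  } else {
    p$Kconv2 <- array(tn_init(9 * Di, sd = 0.1), dim = c(3, 3, Di))
    p$bconv2 <- numeric(Di)
    p$Wpw <- tn_init(Di, Di)
    p$bpw <- numeric(Di)
  }
  attr(p, "variant") <- variant
  attr(p, "meta") <- list(C = C, Di = Di, N = N, R = R)
  p
}

vss_fwd <- function(p, x) {
  meta <- attr(p, "meta"); variant <- attr(p, "variant")
  d <- dim(x); B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  Di <- meta$Di; N <- meta$N; R <- meta$R
  L <- H * W; M <- B * L
  ln1 <- ln_fwd(grid_mat(x), p$ln1_g, p$ln1_b)
  uz <- ln1$y %*% p$Win + rep(p$bin, each = M)
  u0 <- uz[, seq_len(Di), drop = FALSE]
  z <- uz[, Di + seq_len(Di), drop = FALSE]
  u0a <- u0; dim(u0a) <- c(B, H, W, Di)  # M rows enumerate (b, h, w): same memory
  u1 <- dwconv_fwd(u0a, p$Kconv, p$bconv, B, H, W, Di)
  dim(u1) <- c(M, Di)
  uc <- silu(u1)
  uc_seq <- uc; dim(uc_seq) <- c(B, L, Di)  # (h, w) -> natural token order
  dcache <- vector("list", if (variant == "ss2d") 4 else 1)
  if (variant == "ss2d") {
    ords <- scan_orders(H, W)
    ysum <- matrix(0, M, Di)
    for (k in 1:4) {
      pk <- p$dirs[[k]]
      useq <- uc_seq[, ords[[k]], , drop = FALSE]
      um <- useq; dim(um) <- c(M, Di)
      x_dbl <- um %*% pk$Wx
      dt_lin <- x_dbl[, seq_len(R), drop = FALSE] %*% pk$Wdt +
        rep(pk$bdt, each = M)
      delta <- softplus(dt_lin)
      Bm <- x_dbl[, R + seq_len(N), drop = FALSE]
      Cm <- x_dbl[, R + N + seq_len(N), drop = FALSE]
      A <- -exp(pk$Alog)
      sc <- scan_fwd(useq, delta, Bm, Cm, A, pk$Dskip, B, L, Di, N)
      y <- sc$y
      dim(y) <- c(B, L, Di)
      inv <- integer(L); inv[ords[[k]]] <- seq_len(L)
      ynat <- y[, inv, , drop = FALSE]
      dim(ynat) <- c(M, Di)
      ysum <- ysum + ynat
      dcache[[k]] <- list(useq = useq, x_dbl = x_dbl, dt_lin = dt_lin,
                          delta = delta, Bm = Bm, Cm = Cm, A = A,
                          abar = sc$abar, ord = ords[[k]], inv = inv)
    }
  } else {
    uca <- uc; dim(uca) <- c(B, H, W, Di)
    c2 <- dwconv_fwd(uca, p$Kconv2, p$bconv2, B, H, W, Di)
    dim(c2) <- c(M, Di)
    ysum <- c2 %*% p$Wpw + rep(p$bpw, each = M)
    dcache[[1]] <- list(c2 = c2)
  }
  lnO <- ln_fwd(ysum, p$lnO_g, p$lnO_b)
  sz <- silu(z)
  g <- lnO$y * sz
  out <- g %*% p$Wout + rep(p$bout, each = M)
  if (!is.finite(sum(out))) stop("numeric error: non-finite activations in VSS block")
  y <- x + array(out, dim = d)
  list(y = y, cache = list(x = x, ln1 = ln1, u0 = u0, u1 = u1, uc = uc, z = z,
                           ysum = ysum, lnO = lnO, sz = sz, g = g,
                           dirs = dcache, B = B, H = H, W = W, C = C,
                           Di = Di, N = N, R = R, M = M, L = L))
}

vss_bwd <- function(p, cache, dy) {
  variant <- attr(p, "variant")
  ca <- cache
  B <- ca$B; H <- ca$H; W <- ca$W; C <- ca$C
  Di <- ca$Di; N <- ca$N; R <- ca$R; M <- ca$M; L <- ca$L
  dym <- grid_mat(dy)
  g <- list()
  # out_proj
  g$dWout <- crossprod(ca$g, dym); g$dbout <- colSums(dym)
  dg <- tcrossprod(dym, p$Wout)
  # gate
  dlnOy <- dg * ca$sz
  dz <- dg * ca$lnO$y * dsilu(ca$z)
  lo <- ln_bwd(ca$lnO$cache, dlnOy)
  g$dlnO_g <- lo$dg; g$dlnO_b <- lo$db
  dysum <- lo$dx
  duc <- matrix(0, M, Di)
  if (variant == "ss2d") {
    g$ddirs <- vector("list", 4)
    dys <- dysum; dim(dys) <- c(B, L, Di)
    for (k in 1:4) {
      dc <- ca$dirs[[k]]; pk <- p$dirs[[k]]
      dyseq <- dys[, dc$ord, , drop = FALSE]   # route grads through un-permute
      sb <- scan_bwd(dc$useq, dc$delta, dc$Bm, dc$Cm, dc$A, pk$Dskip, dc$abar,
                     dyseq, B, L, Di, N)
      ddelta <- matrix(sb$ddelta, M, Di)
      ddt_lin <- ddelta * sigmoid(dc$dt_lin)
      dx_dbl <- matrix(0, M, R + 2 * N)
      dx_dbl[, seq_len(R)] <- tcrossprod(ddt_lin, pk$Wdt)
      dx_dbl[, R + seq_len(N)] <- matrix(sb$dBm, M, N)
      dx_dbl[, R + N + seq_len(N)] <- matrix(sb$dCm, M, N)
      um <- dc$useq; dim(um) <- c(M, Di)
      duseq <- matrix(sb$du, M, Di) + tcrossprod(dx_dbl, pk$Wx)
      g$ddirs[[k]] <- list(
        dWx = crossprod(um, dx_dbl),
        dWdt = crossprod(dc$x_dbl[, seq_len(R), drop = FALSE], ddt_lin),
        dbdt = colSums(ddt_lin),
        dAlog = sb$dA * dc$A,
        dDskip = sb$dDskip)
      dim(duseq) <- c(B, L, Di)
      dnat <- duseq[, dc$inv, , drop = FALSE]
      dim(dnat) <- c(M, Di)
      duc <- duc + dnat
    }
  } else {
    dc2 <- tcrossprod(dysum, p$Wpw)
    g$dWpw <- crossprod(ca$dirs[[1]]$c2, dysum); g$dbpw <- colSums(dysum)
    uca <- ca$uc; dim(uca) <- c(B, H, W, Di)
    cb <- dwconv_bwd(uca, p$Kconv2, dc2, B, H, W, Di)
    g$dKconv2 <- array(cb$dK, dim = c(3, 3, Di)); g$dbconv2 <- cb$dbias
    duc <- duc + matrix(cb$dx, M, Di)
  }
  du1 <- duc * dsilu(ca$u1)
  u0a <- ca$u0; dim(u0a) <- c(B, H, W, Di)
  cb1 <- dwconv_bwd(u0a, p$Kconv, du1, B, H, W, Di)
  g$dKconv <- array(cb1$dK, dim = c(3, 3, Di)); g$dbconv <- cb1$dbias
  du0 <- matrix(cb1$dx, M, Di)
  duz <- cbind(du0, dz)
  g$dWin <- crossprod(ca$ln1$y, duz); g$dbin <- colSums(duz)
  dln1y <- tcrossprod(duz, p$Win)
  l1 <- ln_bwd(ca$ln1$cache, dln1y)
  g$dln1_g <- l1$dg; g$dln1_b <- l1$db
  dx <- dy + array(l1$dx, dim = dim(dy))  # residual
  list(dx = dx, grads = g)
}

## ---- heads ----

init_feature_head <- function(C, d_f) {
  if (d_f < 2) stop("config error: d_f must be >= 2")
  list(ln_g = rep(1, C), ln_b = numeric(C), W = tn_init(C, d_f),
       b = numeric(d_f))
}

feature_head_fwd <- function(p, x) {
  d <- dim(x); B <- d[1]; L <- d[2] * d[3]; C <- d[4]
  ln <- ln_fwd(grid_mat(x), p$ln_g, p$ln_b)
  ym <- ln$y; dim(ym) <- c(B, L, C)
  pooled <- colMeans(aperm(ym, c(2, 1, 3)), dims = 1)  # [B, C] global avg pool
  f <- pooled %*% p$W + rep(p$b, each = B)
  list(f = f, cache = list(ln = ln, pooled = pooled, B = B, L = L, C = C,
                           d = d))
}

feature_head_bwd <- function(p, cache, df) {
  ca <- cache
  dpooled <- tcrossprod(df, p$W)
  dW <- crossprod(ca$pooled, df); db <- colSums(df)
  # broadcast the pooled gradient back uniformly over tokens
  dym <- aperm(array(dpooled / ca$L, dim = c(ca$B, ca$C, ca$L)), c(1, 3, 2))
  dim(dym) <- c(ca$B * ca$L, ca$C)
  ln <- ln_bwd(ca$ln$cache, dym)
  dx <- array(ln$dx, dim = ca$d)
  list(dx = dx, grads = list(dln_g = ln$dg, dln_b = ln$db, dW = dW, db = db))
}

init_classifier_head <- function(C) {
  list(ln_g = rep(1, C), ln_b = numeric(C), W = tn_init(C, 1), b = numeric(1))
}

classifier_head_fwd <- function(p, x) {
  d <- dim(x); B <- d[1]; L <- d[2] * d[3]; C <- d[4]
  ln <- ln_fwd(grid_mat(x), p$ln_g, p$ln_b)
  ym <- ln$y; dim(ym) <- c(B, L, C)
  pooled <- colMeans(aperm(ym, c(2, 1, 3)), dims = 1)  # adaptive avg pool 1x1
  logit <- as.vector(pooled %*% p$W) + p$b
  P <- pmin(pmax(sigmoid(logit), 1e-7), 1 - 1e-7)
  list(P = P, logit = logit,
       cache = list(ln = ln, pooled = pooled, B = B, L = L, C = C, d = d))
}

classifier_head_bwd <- function(p, cache, dlogit) {
  ca <- cache
  dpooled <- outer(dlogit, as.vector(p$W))
  dW <- crossprod(ca$pooled, matrix(dlogit, ncol = 1))
  db <- sum(dlogit)
  dym <- aperm(array(dpooled / ca$L, dim = c(ca$B, ca$C, ca$L)), c(1, 3, 2))
  dim(dym) <- c(ca$B * ca$L, ca$C)
  ln <- ln_bwd(ca$ln$cache, dym)
  dx <- array(ln$dx, dim = ca$d)
  list(dx = dx, grads = list(dln_g = ln$dg, dln_b = ln$db, dW = dW, db = db))
}
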