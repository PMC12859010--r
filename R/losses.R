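#' Loss weights for the joint objective
#'
#' The joint loss is `lambda * (L_V + L_A + L_D) + lambda1 * L_VA +
#' lambda2 * L_AD + lambda3 * L_VD`. The defaults (1.0, 0.15, 0.1, 0.1) are
#' the calibrated operating point of the method.
#'
#' @param lambda weight of the summed per-dimension cross-entropies.
#' @param lambda1 weight of the V-A circular constraint.
#' @param lambda2 weight of the A-D energy-alignment constraint.
#' @param lambda3 weight of the V-D correlation constraint.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda = 1.0, lambda1 = 0.15, lambda2 = 0.1,
                         lambda3 = 0.1) {
  w <- c(lambda = lambda, lambda1 = lambda1, lambda2 = lambda2,
         lambda3 = lambda3)
  if (any(w < 0)) stop("config error: loss weights must be non-negative")
  structure(as.list(w), class = "loss_weights")
}

as_row_matrix <- function(x, width) {
  if (is.null(dim(x))) matrix(x, ncol = width, byrow = FALSE,
                              nrow = length(x) / width)
  else as.matrix(x)
}

#' Valence-arousal circular (cosine) constraint
#'
#' `1 - (Vp . Vt) / (||Vp|| ||Vt|| + eps)` between the predicted probability
#' vector `Vp = (P_V, P_A)` and the binary target direction `Vt = (y_V,
#' y_A)`. For non-negative inputs the value lies in \[0, 1\]; the all-low
#' label cell (0, 0) makes the term a constant 1 with zero gradient (inert,
#' by design). `eps` guards the denominator so the term is differentiable
#' everywhere.
#'
#' @param Vp numeric length-2 vector or n x 2 matrix of probabilities.
#' @param Vt numeric length-2 vector or n x 2 matrix of binary labels
#'   (optionally remapped; the default pipeline passes raw 0/1).
#' @param eps denominator guard (default 1e-8).
#' @return Per-sample loss values (numeric vector).
#' @export
loss_va_circular <- function(Vp, Vt, eps = 1e-8) {
  Vp <- as_row_matrix(Vp, 2L); Vt <- as_row_matrix(Vt, 2L)
  s <- rowSums(Vp * Vt)
  q <- sqrt(rowSums(Vp^2)) * sqrt(rowSums(Vt^2)) + eps
  1 - s / q
}

grad_va_circular <- function(Vp, Vt, eps = 1e-8) {
  Vp <- as_row_matrix(Vp, 2L); Vt <- as_row_matrix(Vt, 2L)
  s <- rowSums(Vp * Vt)
  np <- sqrt(rowSums(Vp^2)); nt <- sqrt(rowSums(Vt^2))
  q <- np * nt + eps
  -Vt / q + (s * nt / (pmax(np, 1e-300) * q^2)) * Vp
}

#' Arousal-dominance energy-alignment constraint
#'
#' Squared difference of the embedding L2 norms, `(||f_A|| - ||f_D||)^2`:
#' non-negative, zero iff the norms match, and invariant to any rotation of
#' either embedding.
#'
#' @param f_A,f_D numeric vectors or n x d matrices of branch embeddings.
#' @return Per-sample loss values.
#' @export
loss_ad_energy <- function(f_A, f_D) {
  f_A <- as_embed(f_A); f_D <- as_embed(f_D)
  (sqrt(rowSums(f_A^2)) - sqrt(rowSums(f_D^2)))^2
}

as_embed <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)

grad_ad_energy <- function(f_A, f_D) {
  na <- sqrt(rowSums(f_A^2)); nd <- sqrt(rowSums(f_D^2))
  gap <- na - nd
  list(dfA = (2 * gap / pmax(na, 1e-12)) * f_A,
       dfD = (-2 * gap / pmax(nd, 1e-12)) * f_D)
}

#' Valence-dominance correlation constraint
#'
#' `1 - (f_V . f_D) / (||f_V|| ||f_D|| + tau)`: about 0 for aligned
#' embeddings, 1 for orthogonal, about 2 for anti-aligned; `tau` guards the
#' denominator.
#'
#' @param f_V,f_D numeric vectors or n x d matrices of branch embeddings.
#' @param tau denominator guard (default 1e-8).
#' @return Per-sample loss values.
#' @export
loss_vd_corr <- function(f_V, f_D, tau = 1e-8) {
  f_V <- as_embed(f_V); f_D <- as_embed(f_D)
  s <- rowSums(f_V * f_D)
  q <- sqrt(rowSums(f_V^2)) * sqrt(rowSums(f_D^2)) + tau
  1 - s / q
}

grad_vd_corr <- function(f_V, f_D, tau = 1e-8) {
  s <- rowSums(f_V * f_D)
  nv <- sqrt(rowSums(f_V^2)); nd <- sqrt(rowSums(f_D^2))
  q <- nv * nd + tau
  list(dfV = -f_D / q + (s * nd / (pmax(nv, 1e-300) * q^2)) * f_V,
       dfD = -f_V / q + (s * nv / (pmax(nd, 1e-300) * q^2)) * f_D)
}

#' Per-dimension binary cross-entropy
#'
#' `-(y log P + (1 - y) log(1 - P))` after clamping P to
#' \[1e-7, 1 - 1e-7\], so the loss is always finite.
#'
#' @param P predicted probabilities in (0, 1).
#' @param y binary labels.
#' @return Per-sample loss values.
#' @export
bce_dimension <- function(P, y) {
  P <- pmin(pmax(P, 1e-7), 1 - 1e-7)
  -(y * log(P) + (1 - y) * log1p(-P))
}

#' Combine loss terms into the joint objective
#'
#' @param L_V,L_A,L_D per-dimension cross-entropy terms (already reduced).
#' @param L_VA,L_AD,L_VD coupling-constraint terms (already reduced).
#' @param weights a [loss_weights()].
#' @return A `loss_breakdown`: the six unweighted terms plus the weighted
#'   `total`.
#' @export
joint_loss <- function(L_V, L_A, L_D, L_VA, L_AD, L_VD,
                       weights = loss_weights()) {
  if (!inherits(weights, "loss_weights")) weights <- do.call(loss_weights, weights)
  total <- weights$lambda * (L_V + L_A + L_D) + weights$lambda1 * L_VA +
    weights$lambda2 * L_AD + weights$lambda3 * L_VD
  structure(list(L_V = L_V, L_A = L_A, L_D = L_D, L_VA = L_VA, L_AD = L_AD,
                 L_VD = L_VD, total = total, weights = weights),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss_breakdown> total %.6f | BCE V/A/D %.4f/%.4f/%.4f | VA %.4f AD %.4f VD %.4f\n",
              x$total, x$L_V, x$L_A, x$L_D, x$L_VA, x$L_AD, x$L_VD))
  invisible(x)
}

#' Batch loss breakdown
#'
#' Computes every term of the joint objective as the arithmetic mean of
#' per-sample values over a batch, then the weighted total. `ad_mask =
#' "high_arousal_only"` restricts the A-D energy term's mean to samples with
#' `y_A = 1` (an empty mask gives 0); the default `"all"` follows the
#' unconditional formula.
#'
#' @param P numeric n x 3 matrix of probabilities (columns V, A, D).
#' @param f named list with `V`, `A`, `D` embedding matrices (n x d_f).
#' @param labels integer n x 3 matrix of binary labels.
#' @param weights a [loss_weights()].
#' @param eps,tau denominator guards for the cosine terms.
#' @param ad_mask `"all"` or `"high_arousal_only"`.
#' @return A `loss_breakdown`.
#' @export
batch_losses <- function(P, f, labels, weights = loss_weights(),
                         eps = 1e-8, tau = 1e-8,
                         ad_mask = c("all", "high_arousal_only")) {
  ad_mask <- match.arg(ad_mask)
  P <- as_row_matrix(P, 3L); labels <- as_row_matrix(labels, 3L)
  n <- nrow(P)
  if (n == 0L) stop("empty batch")
  L_V <- mean(bce_dimension(P[, 1], labels[, 1]))
  L_A <- mean(bce_dimension(P[, 2], labels[, 2]))
  L_D <- mean(bce_dimension(P[, 3], labels[, 3]))
  L_VA <- mean(loss_va_circular(P[, 1:2], labels[, 1:2], eps))
  ad_vals <- loss_ad_energy(f$A, f$D)
  L_AD <- if (ad_mask == "all") mean(ad_vals) else {
    m <- labels[, 2] == 1L
    if (!any(m)) 0 else mean(ad_vals[m])
  }
  L_VD <- mean(loss_vd_corr(f$V, f$D, tau))
  joint_loss(L_V, L_A, L_D, L_VA, L_AD, L_VD, weights)
}

# Loss + gradients for the training loop. Constraint terms are computed
# (and their gradients propagated) only when the corresponding flag is TRUE;
# a disabled term contributes exactly 0 and its weight is ignored.
# Returns breakdown, dlogits [n, 3] and df (named list, NULL when untouched).
batch_loss_grads <- function(P_raw, logits, f, labels, weights,
                             flags = c(VA = TRUE, AD = TRUE, VD = TRUE),
                             eps = 1e-8, tau = 1e-8, ad_mask = "all") {
  n <- nrow(P_raw)
  P <- pmin(pmax(P_raw, 1e-7), 1 - 1e-7)
  L_V <- mean(bce_dimension(P[, 1], labels[, 1]))
  L_A <- mean(bce_dimension(P[, 2], labels[, 2]))
  L_D <- mean(bce_dimension(P[, 3], labels[, 3]))
  # d(BCE)/dlogit through the sigmoid: (P - y) / n, scaled by lambda
  dlogits <- (weights$lambda / n) * (P_raw - labels)
  df <- list(V = NULL, A = NULL, D = NULL)
  L_VA <- 0; L_AD <- 0; L_VD <- 0
  if (isTRUE(flags[["VA"]])) {
    L_VA <- mean(loss_va_circular(P[, 1:2], labels[, 1:2], eps))
    dVp <- grad_va_circular(P[, 1:2], labels[, 1:2], eps)
    dsig <- P_raw[, 1:2] * (1 - P_raw[, 1:2])
    dlogits[, 1:2] <- dlogits[, 1:2] + (weights$lambda1 / n) * dVp * dsig
  }
  if (isTRUE(flags[["AD"]])) {
    m <- if (ad_mask == "all") rep(TRUE, n) else labels[, 2] == 1L
    vals <- loss_ad_energy(f$A, f$D)
    if (any(m)) {
      L_AD <- mean(vals[m])
      gr <- grad_ad_energy(f$A[m, , drop = FALSE], f$D[m, , drop = FALSE])
      dfA <- matrix(0, n, ncol(f$A)); dfD <- matrix(0, n, ncol(f$D))
      dfA[m, ] <- (weights$lambda2 / sum(m)) * gr$dfA
      dfD[m, ] <- (weights$lambda2 / sum(m)) * gr$dfD
      df$A <- dfA; df$D <- dfD
    }
  }
  if (isTRUE(flags[["VD"]])) {
    L_VD <- mean(loss_vd_corr(f$V, f$D, tau))
    gr <- grad_vd_corr(f$V, f$D, tau)
    df$V <- (weights$lambda3 / n) * gr$dfV
    df$D <- if (is.null(df$D)) (weights$lambda3 / n) * gr$dfD
            else df$D + (weights$lambda3 / n) * gr$dfD
  }
  bd <- joint_loss(L_V, L_A, L_D, L_VA, L_AD, L_VD, weights)
  list(breakdown = bd, dlogits = dlogits, df = df)
}
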