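ns <- asNamespace("eegcouple")

# independent direct-formula evaluators (scalar, straight from the math)
oracle_va <- function(Vp, Vt, eps = 1e-8)
  1 - sum(Vp * Vt) / (sqrt(sum(Vp^2)) * sqrt(sum(Vt^2)) + eps)
oracle_ad <- function(fA, fD) (sqrt(sum(fA^2)) - sqrt(sum(fD^2)))^2
oracle_vd <- function(fV, fD, tau = 1e-8)
  1 - sum(fV * fD) / (sqrt(sum(fV^2)) * sqrt(sum(fD^2)) + tau)
oracle_bce <- function(P, y) {
  P <- min(max(P, 1e-7), 1 - 1e-7)
  -(y * log(P) + (1 - y) * log(1 - P))
}

test_that("loss operations match independent oracles on 1000 random draws", {
  set.seed(101)
  worst <- 0
  for (i in 1:1000) {
    Vp <- runif(2, 0.01, 0.99); Vt <- sample(0:1, 2, TRUE)
    fA <- rnorm(8); fD <- rnorm(8); fV <- rnorm(8)
    P <- runif(1, 0.01, 0.99); y <- sample(0:1, 1)
    pairs <- rbind(
      c(loss_va_circular(Vp, Vt), oracle_va(Vp, Vt)),
      c(loss_ad_energy(fA, fD), oracle_ad(fA, fD)),
      c(loss_vd_corr(fV, fD), oracle_vd(fV, fD)),
      c(bce_dimension(P, y), oracle_bce(P, y)))
    rel <- abs(pairs[, 1] - pairs[, 2]) / pmax(1e-12, abs(pairs[, 2]))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-6)
})

test_that("worked examples evaluate to their hand-computed values", {
  # cosine of (0.6, 0.8) against (1, 0): 1 - 0.6
  expect_equal(loss_va_circular(c(0.6, 0.8), c(1, 0), eps = 0), 0.4)
  # parallel vectors: ~0 (eps-limited)
  expect_lt(loss_va_circular(c(0.9, 0.9), c(1, 1)), 1e-8)
  # norms 5 and 0
  expect_equal(loss_ad_energy(c(3, 4), c(0, 0)), 25)
  expect_equal(bce_dimension(0.5, 1), log(2))
  expect_equal(bce_dimension(0.9, 1), -log(0.9))
  expect_lt(bce_dimension(1 - 1e-7, 1), 1e-6)
})

test_that("degenerate-case contracts hold exactly", {
  # all-low V-A cell: zero numerator makes the term exactly 1
  for (i in 1:20) {
    Vp <- runif(2, 0.01, 0.99)
    expect_identical(loss_va_circular(Vp, c(0, 0)), 1)
  }
  # A-D energy: zero iff norms match, invariant under rotation of either side
  set.seed(6)
  for (i in 1:20) {
    fA <- rnorm(5)
    th <- runif(1, 0, 2 * pi)
    # random rotation in a random coordinate plane
    R <- diag(5); ij <- sample(5, 2)
    R[ij[1], ij[1]] <- cos(th); R[ij[2], ij[2]] <- cos(th)
    R[ij[1], ij[2]] <- -sin(th); R[ij[2], ij[1]] <- sin(th)
    fD <- as.vector(R %*% fA)  # same norm, different direction
    expect_lt(loss_ad_energy(fA, fD), 1e-20)
    fD2 <- rnorm(5)
    expect_equal(loss_ad_energy(fA, as.vector(R %*% fD2)),
                 loss_ad_energy(fA, fD2), tolerance = 1e-10)
    expect_gt(loss_ad_energy(fA, 2 * fA), 0)
  }
  # V-D correlation hits 0 / 1 / 2 at aligned / orthogonal / anti-aligned
  f <- c(1, 2, 2)
  expect_lt(loss_vd_corr(f, 3 * f), 1e-8)
  expect_identical(loss_vd_corr(c(1, 0), c(0, 1)), 1)
  expect_equal(loss_vd_corr(f, -f), 2, tolerance = 1e-8)
})

test_that("loss bounds hold over random inputs (property)", {
  set.seed(77)
  for (i in 1:200) {
    Vp <- runif(2, 0, 1); Vt <- sample(0:1, 2, TRUE)
    v <- loss_va_circular(Vp, Vt)
    expect_gte(v, 0); expect_lte(v, 1 + 1e-12)
    fV <- rnorm(4); fD <- rnorm(4)
    w <- loss_vd_corr(fV, fD)
    expect_gte(w, 0); expect_lte(w, 2 + 1e-12)
    expect_gte(loss_ad_energy(rnorm(4), rnorm(4)), 0)
  }
})

test_that("analytic gradients of the coupling losses match finite differences", {
  set.seed(303)
  h <- 1e-6
  worst <- 0
  for (i in 1:50) {
    # Eq-1-style term, away from the inert (0,0) cell
    Vp <- runif(2, 0.05, 0.95)
    Vt <- if (i %% 3 == 0) c(1, 1) else sample(list(c(1, 0), c(0, 1)))[[1]]
    gan <- ns$grad_va_circular(Vp, Vt)
    for (j in 1:2) {
      e <- numeric(2); e[j] <- h
      fd <- (oracle_va(Vp + e, Vt) - oracle_va(Vp - e, Vt)) / (2 * h)
      worst <- max(worst, abs(fd - gan[j]) / max(1e-8, abs(fd), abs(gan[j])))
    }
    # norm-gap and cosine terms on random embeddings
    fA <- rnorm(5); fD <- rnorm(5); fV <- rnorm(5)
    gad <- ns$grad_ad_energy(matrix(fA, 1), matrix(fD, 1))
    gvd <- ns$grad_vd_corr(matrix(fV, 1), matrix(fD, 1))
    for (j in 1:5) {
      e <- numeric(5); e[j] <- h
      fd <- (oracle_ad(fA + e, fD) - oracle_ad(fA - e, fD)) / (2 * h)
      worst <- max(worst, abs(fd - gad$dfA[j]) / max(1e-8, abs(fd)))
      fd <- (oracle_ad(fA, fD + e) - oracle_ad(fA, fD - e)) / (2 * h)
      worst <- max(worst, abs(fd - gad$dfD[j]) / max(1e-8, abs(fd)))
      fd <- (oracle_vd(fV + e, fD) - oracle_vd(fV - e, fD)) / (2 * h)
      worst <- max(worst, abs(fd - gvd$dfV[j]) / max(1e-8, abs(fd)))
      fd <- (oracle_vd(fV, fD + e) - oracle_vd(fV, fD - e)) / (2 * h)
      worst <- max(worst, abs(fd - gvd$dfD[j]) / max(1e-8, abs(fd)))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("joint loss is the stated weighted sum and validates weights", {
  w <- loss_weights()  # 1.0, 0.15, 0.1, 0.1
  bd <- joint_loss(1, 1, 1, 1, 1, 1, w)
  expect_equal(bd$total, 3.35, tolerance = 1e-12)
  set.seed(12)
  for (i in 1:100) {
    terms <- runif(6, 0, 3)
    wts <- loss_weights(runif(1, 0, 2), runif(1, 0, 1), runif(1, 0, 1),
                        runif(1, 0, 1))
    bd <- do.call(joint_loss, c(as.list(terms), list(weights = wts)))
    manual <- wts$lambda * sum(terms[1:3]) + wts$lambda1 * terms[4] +
      wts$lambda2 * terms[5] + wts$lambda3 * terms[6]
    expect_lt(abs(bd$total - manual), 1e-10)
  }
  # lambda-only weighting reduces to plain multi-task BCE
  bd0 <- joint_loss(0.3, 0.4, 0.5, 9, 9, 9, loss_weights(1, 0, 0, 0))
  expect_equal(bd0$total, 1.2)
  expect_equal(joint_loss(0, 0, 0, 0, 0, 0, w)$total, 0)
  expect_error(loss_weights(lambda1 = -0.1), "non-negative")
})

test_that("batch reduction averages per-sample terms; the A-D mask works", {
  set.seed(44)
  n <- 2
  P <- matrix(runif(n * 3, 0.05, 0.95), n, 3)
  y <- matrix(c(1L, 0L, 1L, 1L, 0L, 1L), n, 3)
  f <- list(V = matrix(rnorm(n * 4), n), A = matrix(rnorm(n * 4), n),
            D = matrix(rnorm(n * 4), n))
  bd <- batch_losses(P, f, y)
  # recompute both samples independently and average
  manual <- sapply(1:n, function(i) c(
    oracle_bce(P[i, 1], y[i, 1]), oracle_bce(P[i, 2], y[i, 2]),
    oracle_bce(P[i, 3], y[i, 3]),
    oracle_va(P[i, 1:2], y[i, 1:2]),
    oracle_ad(f$A[i, ], f$D[i, ]), oracle_vd(f$V[i, ], f$D[i, ])))
  expect_equal(c(bd$L_V, bd$L_A, bd$L_D, bd$L_VA, bd$L_AD, bd$L_VD),
               unname(rowMeans(manual)), tolerance = 1e-10)
  # batch of one equals the per-sample operations
  bd1 <- batch_losses(P[1, , drop = FALSE],
                      lapply(f, function(m) m[1, , drop = FALSE]),
                      y[1, , drop = FALSE])
  expect_equal(bd1$L_AD, oracle_ad(f$A[1, ], f$D[1, ]), tolerance = 1e-10)
  # high-arousal-only mask: restricts the mean; empty mask gives 0
  y2 <- y; y2[, 2] <- c(1L, 0L)
  bdm <- batch_losses(P, f, y2, ad_mask = "high_arousal_only")
  expect_equal(bdm$L_AD, oracle_ad(f$A[1, ], f$D[1, ]), tolerance = 1e-10)
  y3 <- y; y3[, 2] <- 0L
  expect_equal(batch_losses(P, f, y3, ad_mask = "high_arousal_only")$L_AD, 0)
  expect_error(batch_losses(P[0, , drop = FALSE], f, y[0, , drop = FALSE]),
               "empty batch")
})
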