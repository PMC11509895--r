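# Independent oracles, deliberately coded on different paths than the
# package internals they check.

# trig-based wrap to [-180, 180] (package uses modular arithmetic)
oracle_wrap <- function(x) atan2(sin(x * pi / 180), cos(x * pi / 180)) * 180 / pi

# exhaustive 16-way nearest-prototype search, scalar loop with explicit
# minimum tracking
oracle_assign <- function(window, table = pb_reference()) {
  if (anyNA(window)) return("Z")
  best <- NA_character_
  best_d <- Inf
  for (k in seq_len(nrow(table))) {
    proto <- as.numeric(table[k, -1])
    d <- 0
    for (j in 1:8) d <- d + oracle_wrap(window[j] - proto[j])^2
    if (d < best_d) {
      best_d <- d
      best <- table$label[k]
    }
  }
  best
}

# Horn's quaternion method for least-squares rigid superposition RMSD:
# an eigenvalue route fully independent of the SVD-based Kabsch code.
oracle_quaternion_rmsd <- function(mobile, target) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(target, 2, colMeans(target))
  S <- crossprod(X, Y)
  K <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2], S[3, 1] - S[1, 3], S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3], S[1, 2] + S[2, 1], S[3, 1] + S[1, 3],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1], -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[3, 1] + S[1, 3], S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  ss <- sum(X^2) + sum(Y^2) - 2 * lambda
  sqrt(max(0, ss) / nrow(mobile))
}

random_rigid <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  list(R = R, t = rnorm(3, 0, 10))
}

transform_one_frame <- function(ens, frame) {
  rig <- random_rigid()
  ens$xyz[, , frame] <- ens$xyz[, , frame] %*% rig$R +
    matrix(rig$t, dim(ens$xyz)[1], 3, byrow = TRUE)
  ens
}

apply_rigid <- function(ens, rig) {
  for (f in seq_len(n_frames(ens))) {
    ens$xyz[, , f] <- ens$xyz[, , f] %*% rig$R +
      matrix(rig$t, dim(ens$xyz)[1], 3, byrow = TRUE)
  }
  ens
}
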