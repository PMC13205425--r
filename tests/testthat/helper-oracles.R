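# Independent oracles kept deliberately separate from the package internals:
# plain-R nested-loop convolution, scalar kernel-formula evaluation, a
# structure-tensor orientation estimator, and a naive confusion counter.

# true 2-D convolution, replicate padding, anchor floor(m/2) (0-based)
conv2_oracle <- function(img, ker) {
  M <- nrow(img); N <- ncol(img)
  mr <- nrow(ker); mc <- ncol(ker)
  ar <- mr %/% 2; ac <- mc %/% 2
  out <- matrix(0, M, N)
  for (i in seq_len(M)) for (j in seq_len(N)) {
    s <- 0
    for (u in seq_len(mr)) for (v in seq_len(mc)) {
      ii <- min(max(i - (u - 1 - ar), 1), M)
      jj <- min(max(j - (v - 1 - ac), 1), N)
      s <- s + ker[u, v] * img[ii, jj]
    }
    out[i, j] <- s
  }
  out
}

# scalar evaluation of the filter formula at one (x, y) offset
gabor_point <- function(x, y, sigma, theta, lambda, gamma, psi) {
  xp <- x * cos(theta) + y * sin(theta)
  yp <- -x * sin(theta) + y * cos(theta)
  exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) * sin(2 * pi * xp / lambda + psi)
}

# dominant gradient direction (mod pi) from the structure tensor
est_orientation <- function(img) {
  gx <- diff(img)[, -ncol(img), drop = FALSE]
  gy <- t(diff(t(img)))[-nrow(img), , drop = FALSE]
  (0.5 * atan2(2 * sum(gx * gy), sum(gx^2) - sum(gy^2))) %% pi
}

naive_confusion <- function(y_true, y_pred) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1L
    else if (y_true[i] == 0 && y_pred[i] == 1) fp <- fp + 1L
    else if (y_true[i] == 1 && y_pred[i] == 0) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# pure sinusoidal grating image (row coordinate = x)
grating_image <- function(h, w, theta, wavelength, base = 128, amp = 40,
                          phase = 0) {
  x <- matrix(seq_len(h), h, w)
  y <- matrix(seq_len(w), h, w, byrow = TRUE)
  base + amp * sin(2 * pi * (x * cos(theta) + y * sin(theta)) / wavelength +
                     phase)
}

# two well-separated Gaussian feature clouds as a feature table
separable_table <- function(n_per_class = 20, d = 4, gap = 10, sd = 0.1,
                            seed = 1) {
  set.seed(seed)
  x0 <- matrix(rnorm(n_per_class * d, 0, sd), n_per_class, d)
  x1 <- matrix(rnorm(n_per_class * d, gap, sd), n_per_class, d)
  feats <- rbind(x0, x1)
  colnames(feats) <- paste0("f", seq_len(d))
  cbind(data.frame(id = as.character(seq_len(2 * n_per_class))),
        as.data.frame(feats),
        data.frame(label = rep(c(0L, 1L), each = n_per_class)))
}

# fake de_result with just the fields selection/summary code reads
fake_run <- function(fitness, seed) {
  structure(list(best = list(vector = numeric(6), fitness = fitness),
                 seed = as.integer(seed)),
            class = "de_result")
}

bank_fixture <- function(which = "median") {
  read_bank(system.file("extdata", paste0("bank_", which, ".json"),
                        package = "evogmd"))
}
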