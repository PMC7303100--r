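# Independent reference implementation of the 4D convolution, used as the
# oracle for the engine: plain R array arithmetic over explicit patches, no
# shared code with the GEMM path. Layout matches conv4d: input (T, X, Y, Z,
# C), kernel (kt, kx, ky, kz, c_in, c_out).

naive_conv4d <- function(input, kernel, bias = NULL, padding = "same") {
  di <- dim(input); dk <- dim(kernel)
  Tn <- di[1]; X <- di[2]; Y <- di[3]; Z <- di[4]; C <- di[5]
  KT <- dk[1]; KX <- dk[2]; KY <- dk[3]; KZ <- dk[4]; Co <- dk[6]
  if (is.null(bias)) bias <- numeric(Co)
  if (padding == "same") {
    pt <- KT - 1; px <- (KX - 1) / 2; py <- (KY - 1) / 2; pz <- (KZ - 1) / 2
    To <- Tn; Xo <- X; Yo <- Y; Zo <- Z
    pad <- array(0, c(Tn + pt, X + 2 * px, Y + 2 * py, Z + 2 * pz, C))
    pad[pt + seq_len(Tn), px + seq_len(X), py + seq_len(Y), pz + seq_len(Z), ] <- input
  } else {
    To <- Tn - KT + 1; Xo <- X - KX + 1; Yo <- Y - KY + 1; Zo <- Z - KZ + 1
    pad <- input
  }
  out <- array(0, c(To, Xo, Yo, Zo, Co))
  for (o in seq_len(Co)) {
    w <- kernel[, , , , , o, drop = FALSE]
    dim(w) <- dk[1:5]
    for (to in seq_len(To)) for (xo in seq_len(Xo))
      for (yo in seq_len(Yo)) for (zo in seq_len(Zo)) {
        patch <- pad[to + seq_len(KT) - 1, xo + seq_len(KX) - 1,
                     yo + seq_len(KY) - 1, zo + seq_len(KZ) - 1, ,
                     drop = FALSE]
        dim(patch) <- dk[1:5]
        out[to, xo, yo, zo, o] <- sum(patch * w) + bias[o]
      }
  }
  out
}

random_conv_instance <- function() {
  Tn <- sample(1:4, 1); X <- sample(3:6, 1); Y <- sample(3:6, 1); Z <- sample(3:6, 1)
  C <- sample(1:3, 1); Co <- sample(1:4, 1)
  KT <- sample(seq_len(min(2, Tn)), 1)
  same <- runif(1) < 0.5
  ks <- if (same) c(1, 3) else 1:3
  KX <- sample(ks, 1); KY <- sample(ks, 1); KZ <- sample(ks, 1)
  list(input = array(rnorm(Tn * X * Y * Z * C), c(Tn, X, Y, Z, C)),
       kernel = array(rnorm(KT * KX * KY * KZ * C * Co),
                      c(KT, KX, KY, KZ, C, Co)),
       bias = rnorm(Co),
       padding = if (same) "same" else "valid")
}
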