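#' 4D spatio-temporal convolution
#'
#' Convolves a (time, x, y, z, channel) tensor with a 4D kernel spanning the
#' three spatial axes and the temporal axis jointly:
#' \deqn{y[t,x,y,z,o] = b[o] + \sum_{\tau,i,j,k,c} x[t',x+i',y+j',z+k',c]\,
#'   w[\tau,i,j,k,c,o]}
#' With `padding = "same"` the spatial axes are zero-padded symmetrically
#' (odd spatial kernels required) and the temporal axis is zero-padded
#' causally: the output at time t sees input times t-kt+1, ..., t, so a
#' temporal kernel of 1 reduces exactly to an independent per-frame 3D
#' convolution. With `padding = "valid"` every convolved axis shrinks by
#' kernel size minus one. Computed in double precision; the same operator
#' (in single precision) underlies the network layers, where it is
#' differentiated end-to-end by the analytic backward pass.
#'
#' @param input numeric array, dim (T, X, Y, Z, C_in).
#' @param kernel numeric array, dim (kt, kx, ky, kz, C_in, C_out).
#' @param bias per-output-channel offsets, length C_out (default zeros).
#' @param padding `"same"` or `"valid"`.
#' @return Array of dim (T', X', Y', Z', C_out).
#' @export
conv4d <- function(input, kernel, bias = NULL, padding = c("same", "valid")) {
  padding <- match.arg(padding)
  di <- dim(input); dk <- dim(kernel)
  if (length(di) != 5) stop("input must be a 5D (time, x, y, z, channel) array")
  if (length(dk) != 6) stop("kernel must be a 6D (kt, kx, ky, kz, c_in, c_out) array")
  if (dk[5] != di[5])
    stop(sprintf("kernel input channels (%d) do not match input channels (%d)",
                 dk[5], di[5]))
  if (is.null(bias)) bias <- numeric(dk[6])
  if (length(bias) != dk[6]) stop("bias length must equal output channels")

  x <- aperm(input, c(2, 3, 4, 1, 5))                 # -> (X, Y, Z, T, C)
  dim(x) <- c(dim(x), 1)                              # batch of one
  w <- aperm(kernel, c(2, 3, 4, 1, 5, 6))             # -> (kx, ky, kz, kt, ci, co)
  y <- cpp_conv_fwd(x, dim(x), w, dim(w), as.numeric(bias),
                    padding == "same", FALSE)
  dy <- dim(y)
  dim(y) <- dy[1:5]
  aperm(y, c(4, 1, 2, 3, 5))                          # -> (T', X', Y', Z', C')
}

# ---- internal layer primitives on the engine layout (X, Y, Z, T, C, B) -----

conv_fwd_ <- function(x, w, b, same = TRUE, single = TRUE) {
  cpp_conv_fwd(x, dim(x), w, dim(w), b, same, single)
}

conv_bwd_ <- function(x, w, dy, need_dx, same = TRUE, single = TRUE) {
  cpp_conv_bwd(x, dim(x), w, dim(w), dy, need_dx, same, single)
}

pool_fwd_ <- function(x, factor, pool_time) cpp_pool_fwd(x, dim(x), factor, pool_time)

pool_bwd_ <- function(dy, xdim, factor, pool_time) cpp_pool_bwd(dy, xdim, factor, pool_time)

relu_fwd_ <- function(x) cpp_relu_fwd(x)

# dy masked by the forward activation (y > 0)
relu_bwd_ <- function(dy, y) cpp_relu_bwd(dy, y)

# global average pooling: (X,Y,Z,T,C,B) -> C x B feature matrix
gap_fwd_ <- function(x) {
  d <- dim(x)
  m <- prod(d[1:4])
  matrix(colMeans(matrix(x, m, d[5] * d[6])), d[5], d[6])
}

gap_bwd_ <- function(dF, xdim) {
  m <- prod(xdim[1:4])
  dx <- rep(as.vector(dF) / m, each = m)
  dim(dx) <- xdim
  dx
}

# concatenate two activation arrays along the channel axis (axis 5)
concat_c_ <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:4], da[5] + db[5], da[6]))
  out[, , , , seq_len(da[5]), ] <- a
  out[, , , , da[5] + seq_len(db[5]), ] <- b
  out
}
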