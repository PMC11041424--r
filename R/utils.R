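# Internal numerical helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL uses the current stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

# Glorot (uniform) initialisation for a fanIn x fanOut kernel.
glorot <- function(fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(fanIn * fanOut, -lim, lim), fanIn, fanOut)
}

# Adam optimizer state over an arbitrarily nested list of numeric arrays.
adamInit <- function(params) {
  zeros <- rapply(params, function(p) p * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adamStep <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                     epsilon = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + epsilon), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else upd(p, g, m, v)
  }
  out <- walk(params, grads, state$m, state$v)
  state$m <- out$m
  state$v <- out$v
  list(params = out$p, state = state)
}

# Order-stable numeric signature of a parameter list; used to assert the
# frozen-backbone contract cheaply (bit-identity is asserted with identical()).
paramChecksum <- function(params) {
  x <- unlist(params, use.names = FALSE)
  c(sum = sum(x), sumsq = sum(x * x), n = length(x))
}

# Pairwise Euclidean distance between corresponding rows of two matrices.
rowDistance <- function(a, b) sqrt(rowSums((a - b)^2))

# Trapezoid area under y(x) for x increasing.
trapezoid <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
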