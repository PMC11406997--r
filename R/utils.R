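# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All stochastic stages draw their seed from a single master seed through
#' named substreams, so each stage is independently reproducible.
#'
#' @param seed master integer seed.
#' @param stream character stream name, e.g. "pangenome", "counts".
#' @return an integer seed below 2^31.
#' @keywords internal
substream_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(seed) * 2017 + h * 131) %% 2147483629)
}

# Evaluate expr under a local RNG state seeded from (seed, stream);
# restores the caller's RNG afterwards.
with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  expr
}

# row-wise sample variance of a numeric matrix
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all permutations of 1..n as an n! x n integer matrix (n small)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  k <- nrow(sub)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * k + 1L):(i * k)
    rest <- seq_len(n)[-i]
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(rest[sub], nrow = k)
  }
  out
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# The 23 COG functional categories used for cluster annotation ("NA" is
# carried separately as an unassigned group).
cog_categories <- function() {
  c("C", "D", "E", "F", "G", "H", "I", "J", "K", "L", "M", "N", "O",
    "P", "Q", "R", "S", "T", "U", "V", "W", "X", "Z")
}
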