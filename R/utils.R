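# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Gauss-Legendre nodes/weights on [a, b] via the Golub-Welsch eigenvalue
# construction (symmetric tridiagonal Jacobi matrix).
gauss_legendre <- function(n, a = -1, b = 1) {
  stopifnot(n >= 1)
  if (n == 1L) {
    x <- 0; w <- 2
  } else {
    k <- seq_len(n - 1)
    beta <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1)] <- beta
    J[cbind(k + 1, k)] <- beta
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- 2 * e$vectors[1, ]^2
    o <- order(x)
    x <- x[o]; w <- w[o]
  }
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

# strand-aware, case-preserving reverse complement of a plain character string
revcomp_chr <- function(s) {
  chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
         "TGCAYRSWMKVHDBNtgcayrswmkvhdbn",
         vapply(s, function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                     collapse = ""), character(1), USE.NAMES = FALSE))
}

complement_chr <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

round_half_up <- function(x) floor(x + 0.5)

# sample from the elements of x (never from 1:x when x is scalar)
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}
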