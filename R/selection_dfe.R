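# Direction of Selection and gamma distribution-of-fitness-effects
# inference from paired neutral/selected site-frequency spectra.
#
# Model: under the Poisson Random Field, the expected number of selected
# variants at sample count i is theta_sel * r_i * E_i where
#   E_i(S) = integral_0^1 C(n,i) x^i (1-x)^{n-i} H(x; S) dx,
#   H(x; S) = (exp(-S x) - exp(-S)) / ((1 - exp(-S)) x (1 - x)),
# the diffusion sojourn density for a deleterious allele opposed with
# scaled strength S = 4Ns >= 0 (E_i -> 1/i as S -> 0).  The DFE mixes
# E_i(S) over a gamma distribution with shape beta and mean S_mean.
# Per-class multipliers r_i (r_1 = 1), shared by the neutral and selected
# spectra, absorb demography and ascertainment.

#' Direction of Selection
#'
#' `DoS = Dn/(Dn + Ds) - Pn/(Pn + Ps)`.  Negative values indicate an
#' excess of non-synonymous polymorphism relative to divergence, the
#' signature of segregating deleterious variants.
#'
#' @param Dn,Ds Non-synonymous / synonymous fixed differences.
#' @param Pn,Ps Non-synonymous / synonymous polymorphisms.
#' @return A number in \[-1, 1\].
#' @examples
#' dos(10, 10, 10, 10)  # 0
#' @export
dos <- function(Dn, Ds, Pn, Ps) {
  if (any(c(Dn, Ds, Pn, Ps) < 0)) stop("dos: negative count")
  if (Dn + Ds <= 0) stop("dos: divergence denominator Dn + Ds is zero")
  if (Pn + Ps <= 0) stop("dos: polymorphism denominator Pn + Ps is zero")
  Dn / (Dn + Ds) - Pn / (Pn + Ps)
}

#' Expected site-frequency spectrum under constant selection
#'
#' The Poisson Random Field expectation `E_i(S)` for sample size `n`
#' (unfolded classes `i = 1..n-1`), scaled so that `E_i(0) = 1/i`.
#' Numerically stable for `S` up to at least `1e6`: for large `S` the
#' integrand concentrates near the origin and the integral is split
#' there.
#'
#' @param S Scaled strength of selection against the derived allele
#'   (>= 0).
#' @param n Sample size in chromosomes (>= 2).
#' @return Numeric vector of length `n - 1`.
#' @export
expected_sfs <- function(S, n) {
  stopifnot(S >= 0, n >= 2)
  i <- seq_len(n - 1L)
  if (S < 1e-8) return(1 / i)
  # H(x;S) * x(1-x) = (exp(-Sx) - exp(-S)) / (1 - exp(-S)), bounded in [0,1]
  em <- -expm1(-S)  # 1 - exp(-S)
  g <- function(x) (exp(-S * x) - exp(-S)) / em
  vapply(i, function(ii) {
    f <- function(x) exp(lchoose(n, ii) + (ii - 1) * log(x) +
                           (n - ii - 1) * log1p(-x)) * g(x)
    if (S > 20) {
      cut <- min(0.5, 30 / S)
      stats::integrate(f, 0, cut, rel.tol = 1e-9, subdivisions = 400L)$value +
        stats::integrate(f, cut, 1, rel.tol = 1e-9, subdivisions = 400L)$value
    } else {
      stats::integrate(f, 0, 1, rel.tol = 1e-9, subdivisions = 400L)$value
    }
  }, numeric(1))
}

# Gauss-Legendre nodes on log S over [S_lo, S_hi]; cached with the per-n
# matrix of expected_sfs values at the nodes.  Tail mass below S_lo is
# treated as neutral (E_i = 1/i), above S_hi as E_i(S_hi).
dfe_nodes <- function(n, n_nodes = 64L, S_lo = 1e-4, S_hi = 1e6) {
  key <- paste(n, n_nodes, S_lo, S_hi, sep = "_")
  hit <- .domseln_cache$dfe_nodes[[key]]
  if (!is.null(hit)) return(hit)
  gl <- gauss_legendre(n_nodes, log(S_lo), log(S_hi))
  Smat <- exp(gl$nodes)
  E <- vapply(Smat, expected_sfs, numeric(n - 1L), n = n)  # (n-1) x n_nodes
  out <- list(S = Smat, w = gl$weights, E = E, S_lo = S_lo, S_hi = S_hi,
              E_hi = expected_sfs(S_hi, n), n = n)
  if (is.null(.domseln_cache$dfe_nodes))
    .domseln_cache$dfe_nodes <- list()
  .domseln_cache$dfe_nodes[[key]] <- out
  out
}

# E_i mixed over Gamma(shape = beta, mean = S_mean)
gamma_mixed_sfs <- function(beta, S_mean, n, nodes = NULL) {
  i <- seq_len(n - 1L)
  if (S_mean <= 0) return(1 / i)
  if (is.null(nodes)) nodes <- dfe_nodes(n)
  rate <- beta / S_mean
  dens <- stats::dgamma(nodes$S, shape = beta, rate = rate)
  quad <- as.vector(nodes$E %*% (nodes$w * dens * nodes$S))
  lo_mass <- stats::pgamma(nodes$S_lo, shape = beta, rate = rate)
  hi_mass <- stats::pgamma(nodes$S_hi, shape = beta, rate = rate,
                           lower.tail = FALSE)
  quad + lo_mass / i + hi_mass * nodes$E_hi
}

# expected observed-class means for an sfs_pair under the model
dfe_means <- function(beta, S_mean, theta_sel, theta_neu, r, pair,
                      nodes = NULL) {
  n <- pair$n
  i <- seq_len(n - 1L)
  base_neu <- theta_neu / i
  base_sel <- theta_sel * gamma_mixed_sfs(beta, S_mean, n, nodes)
  if (pair$folded) {
    base_neu <- fold_vector(base_neu, n)
    base_sel <- fold_vector(base_sel, n)
  }
  list(neutral = r * base_neu, selected = r * base_sel)
}

#' Poisson log-likelihood of a paired site-frequency spectrum
#'
#' Neutral class `i` has mean `theta_neu * r_i / i`; selected class `i`
#' has mean `theta_sel * r_i * E_i` with `E_i` the gamma-mixed sojourn
#' expectation.  For folded spectra, complementary unfolded means are
#' summed before the distortions `r` (which then have one entry per
#' folded class) are applied.
#'
#' @param params List (or named vector) with `beta`, `S_mean`,
#'   `theta_sel`, `theta_neu`, and optionally `r` (per observed class,
#'   `r[1]` conventionally 1; default all 1).
#' @param sfs_pair An [sfs_pair()].
#' @return Scalar log-likelihood.
#' @export
dfe_loglik <- function(params, sfs_pair) {
  p <- as.list(params)
  nobs <- length(sfs_pair$neutral)
  r <- p$r %||% rep(1, nobs)
  stopifnot(length(r) == nobs, all(r > 0))
  mu <- dfe_means(p$beta, p$S_mean, p$theta_sel, p$theta_neu, r, sfs_pair)
  if (any(!is.finite(mu$neutral)) || any(!is.finite(mu$selected)))
    stop("dfe_loglik: non-finite expected count")
  sum(stats::dpois(sfs_pair$neutral, mu$neutral, log = TRUE)) +
    sum(stats::dpois(sfs_pair$selected, mu$selected, log = TRUE))
}

#' DFE fitting configuration
#'
#' @param n_nodes Quadrature nodes on log S for the gamma mixture.
#' @param S_bounds Integration bounds for S.
#' @param fit_distortions Estimate per-class `r` multipliers (`r[1]`
#'   fixed at 1) alongside the DFE.
#' @param n_starts Number of deterministic starting points.
#' @param n_boot Parametric-bootstrap replicates for standard errors on
#'   the category proportions (0 disables; 200 is a sensible choice when
#'   intervals are needed).
#' @param seed Seed for the bootstrap.
#' @return List of class `dfe_config`.
#' @export
dfe_config <- function(n_nodes = 64L, S_bounds = c(1e-4, 1e6),
                       fit_distortions = TRUE, n_starts = 8L, n_boot = 0L,
                       seed = 1L) {
  structure(list(n_nodes = as.integer(n_nodes), S_bounds = S_bounds,
                 fit_distortions = isTRUE(fit_distortions),
                 n_starts = as.integer(n_starts), n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "dfe_config")
}

#' Fit a gamma DFE to a paired site-frequency spectrum
#'
#' Maximizes [dfe_loglik()] over `(beta, S_mean, theta_sel, theta_neu)`
#' and, optionally, the per-class distortions `r[2..]`, by bounded
#' quasi-Newton (`L-BFGS-B` on log-transformed parameters) from a
#' deterministic grid of starting points.  The gamma mixture uses
#' fixed-node Gauss-Legendre quadrature on log S.  Deterministic given
#' the input and configuration.
#'
#' @param pair An [sfs_pair()] with at least 4 classes.
#' @param config A [dfe_config()].
#' @return Object of class `dfe_fit`: estimates, log-likelihood,
#'   `converged` flag, `category_proportions` over |S| in \[0,1), \[1,10),
#'   \[10,100), \[100,Inf) (with bootstrap SEs when `n_boot > 0`).
#' @export
fit_dfe <- function(pair, config = dfe_config()) {
  stopifnot(inherits(pair, "sfs_pair"))
  nobs <- length(pair$neutral)
  if (nobs < 4) stop("fit_dfe: need at least 4 frequency classes")
  nodes <- dfe_nodes(pair$n, config$n_nodes, config$S_bounds[1],
                     config$S_bounds[2])
  i_obs <- seq_len(nobs)
  shape_neu <- if (pair$folded) fold_vector(1 / seq_len(pair$n - 1L), pair$n)
               else 1 / i_obs
  theta_neu0 <- max(sum(pair$neutral) / sum(shape_neu), 1e-3)
  theta_sel0 <- max(sum(pair$selected) / sum(shape_neu), 1e-3)
  k_r <- if (config$fit_distortions) nobs - 1L else 0L

  unpack <- function(x) {
    r <- rep(1, nobs)
    if (k_r > 0) r[-1] <- exp(x[4 + seq_len(k_r)])
    list(beta = exp(x[1]), S_mean = exp(x[2]), theta_sel = exp(x[3]),
         theta_neu = exp(x[4]), r = r)
  }
  negll <- function(x) {
    p <- unpack(x)
    mu <- dfe_means(p$beta, p$S_mean, p$theta_sel, p$theta_neu, p$r, pair,
                    nodes)
    if (any(!is.finite(mu$neutral)) || any(!is.finite(mu$selected)) ||
        any(mu$neutral <= 0) || any(mu$selected <= 0)) return(1e12)
    -(sum(stats::dpois(pair$neutral, mu$neutral, log = TRUE)) +
        sum(stats::dpois(pair$selected, mu$selected, log = TRUE)))
  }
  beta_grid <- c(0.1, 0.3, 1, 0.05, 0.5, 2, 0.2, 3)
  S_grid <- c(10, 100, 1, 1000, 50, 5, 500, 1e4)
  starts <- lapply(seq_len(config$n_starts), function(s) {
    k <- (s - 1L) %% 8L + 1L
    c(log(beta_grid[k]), log(S_grid[k]), log(theta_sel0), log(theta_neu0),
      rep(0, k_r))
  })
  lower <- c(log(1e-3), log(1e-4), log(1e-8), log(1e-8), rep(-4, k_r))
  upper <- c(log(50), log(1e6), log(1e12), log(1e12), rep(4, k_r))
  best <- NULL
  conv <- FALSE
  for (x0 in starts) {
    fit <- tryCatch(
      stats::optim(x0, negll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-9) {
      best <- fit
      conv <- fit$convergence == 0L
    }
  }
  if (is.null(best)) stop("fit_dfe: all starts failed")
  est <- unpack(best$par)
  props <- category_proportions(est$beta, est$S_mean)
  out <- list(beta = est$beta, S_mean = est$S_mean,
              theta_sel = est$theta_sel, theta_neu = est$theta_neu,
              r = est$r, log_likelihood = -best$value, converged = conv,
              category_proportions = props, category_se = NULL,
              n = pair$n, folded = pair$folded, config = config)
  class(out) <- "dfe_fit"
  if (config$n_boot > 0L) {
    boots <- with_seed(config$seed, {
      vapply(seq_len(config$n_boot), function(b) {
        mu <- dfe_means(est$beta, est$S_mean, est$theta_sel, est$theta_neu,
                        est$r, pair, nodes)
        bp <- sfs_pair(pair$n, stats::rpois(nobs, mu$neutral),
                       stats::rpois(nobs, mu$selected), folded = pair$folded)
        bc <- config; bc$n_boot <- 0L
        bf <- fit_dfe(bp, bc)
        bf$category_proportions
      }, numeric(4))
    })
    out$category_se <- apply(boots, 1, stats::sd)
  }
  out
}

#' @export
print.dfe_fit <- function(x, ...) {
  cat(sprintf("dfe_fit: shape %.3f, mean |S| %.3g, logLik %.2f%s\n",
              x$beta, x$S_mean, x$log_likelihood,
              if (x$converged) "" else " (NOT converged)"))
  p <- x$category_proportions
  cat(sprintf("  |S|<1: %.3f  [1,10): %.3f  [10,100): %.3f  >=100: %.3f\n",
              p[1], p[2], p[3], p[4]))
  invisible(x)
}

#' Gamma-DFE mass in the standard |S| categories
#'
#' Gamma CDF differences over \[0,1), \[1,10), \[10,100), \[100,Inf).
#'
#' @param beta Gamma shape (> 0).
#' @param S_mean Gamma mean (>= 0); 0 degenerates to all mass in \[0,1).
#' @param breaks Category boundaries, default `c(1, 10, 100)`.
#' @return Numeric vector of 4 proportions summing to 1.
#' @export
category_proportions <- function(beta, S_mean, breaks = c(1, 10, 100)) {
  if (S_mean <= 0) return(c(1, rep(0, length(breaks))))
  cdf <- stats::pgamma(breaks, shape = beta, rate = beta / S_mean)
  diff(c(0, cdf, 1))
}

#' Read / write the SFS TSV dialect
#'
#' Columns: `class_index`, `neutral`, `selected`; `n` and `folded` ride
#' in a `# n=<n> folded=<0|1>` header comment.
#' @param pair An [sfs_pair()].
#' @param path TSV path.
#' @export
write_sfs <- function(pair, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d folded=%d", pair$n, as.integer(pair$folded)),
             con)
  utils::write.table(data.frame(class_index = seq_along(pair$neutral),
                                neutral = pair$neutral,
                                selected = pair$selected),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sfs
#' @return `read_sfs` returns the [sfs_pair()].
#' @export
read_sfs <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("n=([0-9]+) folded=([01])", hdr))[[1]]
  if (length(m) != 3) stop("read_sfs: malformed header: ", hdr)
  d <- utils::read.delim(path, sep = "\t", comment.char = "#")
  sfs_pair(as.integer(m[2]), d$neutral, d$selected,
           folded = m[3] == "1")
}

#' Build the paired SFS from classified variants
#'
#' Synonymous variants form the neutral spectrum, non-synonymous the
#' selected one, binned by minor allele count (folded).  Large samples
#' are projected down to `project_to` chromosomes by hypergeometric
#' subsampling (the standard SFS projection; variants monomorphic in the
#' subsample are lost), which keeps the class count — and hence the
#' number of nuisance distortions and sojourn integrals — manageable.
#'
#' @param classified [classify_variants()] output for one region (or all).
#' @param n_chrom Sample size in chromosomes.
#' @param project_to Target sample size for projection (even; default 32;
#'   no-op when `n_chrom <= project_to`).
#' @return A folded [sfs_pair()].
#' @export
sfs_from_classified <- function(classified, n_chrom, project_to = 32L) {
  minor <- pmin(classified$alt_count, classified$allele_number -
                  classified$alt_count)
  minor <- pmax(minor, 1L)
  if (n_chrom <= project_to) {
    m <- n_chrom %/% 2L
    bin <- function(eff)
      tabulate(minor[classified$effect == eff], nbins = m)
    return(sfs_pair(n_chrom, bin("synonymous"), bin("nonsynonymous"),
                    folded = TRUE))
  }
  m <- as.integer(project_to)
  if (m %% 2L == 1L) m <- m - 1L
  half <- m %/% 2L
  # folded projection: minor count i of n -> hypergeometric count j of m,
  # classes j and m-j summed, j in {0, m} dropped
  proj_row <- function(i) {
    q <- stats::dhyper(0:m, i, n_chrom - i, m)
    out <- numeric(half)
    for (j in seq_len(half))
      out[j] <- if (j == m - j) q[j + 1] else q[j + 1] + q[m - j + 1]
    out
  }
  bin <- function(eff) {
    x <- minor[classified$effect == eff]
    tab <- table(x)
    acc <- numeric(half)
    for (k in seq_along(tab))
      acc <- acc + as.integer(tab[k]) * proj_row(as.integer(names(tab)[k]))
    round(acc)
  }
  sfs_pair(m, bin("synonymous"), bin("nonsynonymous"), folded = TRUE)
}
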