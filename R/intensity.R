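#' Build a transition intensity matrix
#'
#' Constructs the generator (intensity) matrix Q of the continuous-time
#' Markov model under the proportional-intensities covariate model
#' \deqn{q_{rs}(z) = q^{(0)}_{rs} \exp(\beta_{rs}^T z),}
#' where \eqn{q^{(0)}_{rs}} is the baseline intensity of the allowed
#' transition r->s and \eqn{\beta_{rs}} collects the log intensity ratios
#' of the covariates attached to that transition.  Off-diagonal entries of
#' disallowed transitions are exactly zero; each row sums to zero;
#' absorbing-state rows are zero.
#'
#' @param spec A [model_spec()].
#' @param params Flat numeric parameter vector in the layout of
#'   [param_names()] (log baselines then betas), or a list with elements
#'   `log_baseline` and `beta`.
#' @param covariates Named numeric vector of covariate values `z`
#'   (defaults: all zero, giving the baseline matrix).
#' @return An `n_states` x `n_states` intensity matrix (per year).
#' @export
build_intensity_matrix <- function(spec, params, covariates = NULL) {
  if (is.list(params)) params <- c(params$log_baseline, params$beta)
  p <- .split_params(spec, params)
  z <- setNames(numeric(length(spec$covariates)), spec$covariates)
  if (!is.null(covariates)) {
    if (is.null(names(covariates)) && length(covariates) == length(z))
      names(covariates) <- spec$covariates
    unknown <- setdiff(names(covariates), spec$covariates)
    if (length(unknown))
      stop("unknown covariates: ", paste(unknown, collapse = ", "))
    z[names(covariates)] <- covariates
  }
  eta <- p$log_baseline
  if (nrow(spec$beta_map)) {
    shift <- p$beta[spec$beta_map$param] * z[spec$beta_map$covariate]
    eta_add <- tapply(shift, spec$beta_map$transition, sum)
    eta[names(eta_add)] <- eta[names(eta_add)] + eta_add
  }
  q <- matrix(0, spec$n_states, spec$n_states)
  q[spec$transitions] <- exp(eta)
  diag(q) <- -rowSums(q)
  q
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computes the matrix of probabilities of occupying state s at elapsed
#' time t given occupancy of state r at time 0, as the matrix exponential
#' of Q t (scaling-and-squaring Pade approximation via [Matrix::expm()];
#' no diagonalizability assumption).
#'
#' @param q Intensity matrix (rows summing to zero, non-negative
#'   off-diagonals).
#' @param t Non-negative elapsed time.
#' @return A stochastic matrix: entries in \[0, 1\], rows summing to 1.
#' @export
transition_probability <- function(q, t) {
  q <- as.matrix(q)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("'t' must be a single non-negative number")
  if (nrow(q) != ncol(q)) stop("'q' must be square")
  if (any(q[row(q) != col(q)] < 0))
    stop("off-diagonal intensities must be non-negative")
  if (max(abs(rowSums(q))) > 1e-8 * max(1, max(abs(q))))
    stop("intensity matrix rows must sum to zero")
  p <- as.matrix(Matrix::expm(q * t))
  # clamp tiny negative round-off
  p[p < 0] <- 0
  p[p > 1] <- 1
  dimnames(p) <- dimnames(q)
  p
}

# Batched transition probabilities for a single Q and many elapsed times.
#
# Returns an (n^2 x T) matrix whose column j is P(t_j) in column-major
# layout: entry (r + (s-1) n, j) = P_{rs}(t_j).  Uses the spectral
# decomposition of Q when Q is reliably diagonalizable with real,
# well-separated eigenvalues (always true generically for progressive
# models, whose Q is triangular up to state relabelling); falls back to
# the Pade matrix exponential per unique time otherwise.
.pmat_batch <- function(q, times) {
  n <- nrow(q)
  ee <- tryCatch(eigen(q), error = function(e) NULL)
  use_eigen <- FALSE
  if (!is.null(ee) &&
      all(abs(Im(ee$values)) <= 1e-12 * (1 + max(abs(ee$values))))) {
    lam <- Re(ee$values)
    v <- Re(ee$vectors)
    vinv <- tryCatch(solve(v), error = function(e) NULL)
    if (!is.null(vinv)) {
      # accept the spectral route only when it reproduces Q accurately
      # (guards against defective or ill-conditioned eigenbases; a
      # repeated eigenvalue with full geometric multiplicity passes)
      recon <- v %*% (lam * vinv)
      if (max(abs(recon - q)) <= 1e-9 * (1 + max(abs(q))))
        use_eigen <- TRUE
    }
  }
  if (use_eigen) {
    # W[, k] = vec(outer(v[, k], vinv[k, ])) so that
    # P(t) = sum_k W[, k] * exp(lam_k t)
    w <- vapply(seq_len(n),
                function(k) as.vector(outer(v[, k], vinv[k, ])),
                numeric(n * n))
    p <- w %*% exp(outer(lam, times))
  } else {
    ut <- unique(times)
    cols <- vapply(ut,
                   function(t) as.vector(as.matrix(Matrix::expm(q * t))),
                   numeric(n * n))
    p <- cols[, match(times, ut), drop = FALSE]
  }
  p[p < 0] <- 0
  p[p > 1] <- 1
  p
}
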