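# FastICA: fixed-point ICA with the logcosh contrast and symmetric
# decorrelation. Input X is observations x variables, already centred
# (and typically column-standardized). Returns the k x p mixing matrix A
# such that X ~ S A with S the n x k matrix of unit-variance sources.
fastIca <- function(X, k, maxit = 1000L, tol = 1e-6, alpha = 1) {
    n <- nrow(X); p <- ncol(X)
    assertThat(n > k, "need more observations than components")
    assertThat(k >= 1 && k <= p, "k must be in 1..ncol(X)")

    ## whiten: Z = X K with cov(Z) = I
    X <- sweep(X, 2, colMeans(X))
    eg <- eigen(crossprod(X) / n, symmetric = TRUE)
    ev <- eg$values[seq_len(k)]
    assertThat(all(ev > 1e-12), "data rank below requested component count")
    K <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(1 / sqrt(ev), k)
    Z <- X %*% K

    ## symmetric orthogonalization helper: W <- (W W^T)^{-1/2} W
    sym <- function(W) {
        s <- eigen(tcrossprod(W), symmetric = TRUE)
        s$vectors %*% diag(1 / sqrt(s$values), k) %*% t(s$vectors) %*% W
    }
    W <- sym(matrix(rnorm(k * k), k, k))
    it <- 0L; delta <- Inf
    while (it < maxit) {
        it <- it + 1L
        U <- Z %*% t(W)                 # n x k projections
        G <- tanh(alpha * U)
        gp <- alpha * (1 - G^2)
        W1 <- sym(crossprod(G, Z) / n - diag(colMeans(gp), k) %*% W)
        delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
        W <- W1
        if (delta < tol) break
    }
    S <- Z %*% t(W)                     # n x k, unit variance by construction
    A <- crossprod(S, X) / n            # least-squares mixing, k x p
    list(A = A, S = S, iterations = it, delta = delta,
         converged = delta < tol)
}

#' Fit ICA components to regional measures and extract gyrus weights
#'
#' Runs an independent component analysis over the pooled participants x
#' regions matrix of one measure (columns z-scored first) and converts the
#' mixing matrix to non-negative relative weights: the weight of region
#' \eqn{g} in component \eqn{c} is \eqn{|a_{cg}| / \sum_g |a_{cg}|}, which
#' resolves ICA's sign and scale indeterminacy. Each row therefore sums
#' to 1. Component order is itself arbitrary under ICA, so components are
#' reported sorted by decreasing total absolute mixing mass (stable
#' ordering). Missing values (e.g. from outlier removal) are mean-imputed
#' per region for the fit. Deterministic given `seed`.
#'
#' @param x a [CorticalCohort-class] (pooled over groups) or a numeric
#'   regions x participants matrix.
#' @param measure assay name when `x` is a cohort.
#' @param k number of components (default 20).
#' @param seed RNG seed for the unmixing initialisation.
#' @param maxit,tol fixed-point iteration cap and convergence tolerance.
#' @param onNoConvergence what to do when the fixed-point iteration hits
#'   `maxit` without meeting `tol`: `"warn"` (default) keeps the final
#'   rotation -- on data with little excess kurtosis the contrast surface
#'   is nearly flat and the rotation, while not a stable fixed point, is
#'   still an orthonormal basis whose absolute-weight summaries are
#'   seeded-deterministic -- or `"error"`, which aborts with the
#'   iteration diagnostics.
#' @return k x regions matrix of relative weights, rows summing to 1.
#' @export
fitComponents <- function(x, measure = "thickness", k = 20, seed = 1,
                          maxit = 200L, tol = 1e-4,
                          onNoConvergence = c("warn", "error")) {
    onNoConvergence <- match.arg(onNoConvergence)
    mat <- if (is.matrix(x)) x else assay(x, measure)
    if (anyNA(mat)) {
        ## scattered missingness from outlier removal: mean-impute per
        ## region for the component fit only
        rm_ <- rowMeans(mat, na.rm = TRUE)
        nas <- which(is.na(mat))
        mat[nas] <- rm_[((nas - 1L) %% nrow(mat)) + 1L]
    }
    Xt <- scale(t(mat))                 # participants x regions, z-scored
    res <- withSeed(seed, fastIca(Xt, k = k, maxit = maxit, tol = tol))
    if (!res$converged) {
        msg <- sprintf(
            "FastICA did not converge: %d iterations, last step %.2e (tol %.2e)",
            res$iterations, res$delta, tol)
        if (onNoConvergence == "error") stop(msg, call. = FALSE)
        warning(msg, call. = FALSE)
    }
    A <- abs(res$A)
    W <- A / rowSums(A)
    ord <- order(rowSums(A), decreasing = TRUE)
    W <- W[ord, , drop = FALSE]
    dimnames(W) <- list(paste0("IC", seq_len(k)), rownames(mat))
    W
}
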