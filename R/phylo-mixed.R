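#' @include AllClasses.R
NULL

#' Phylogenetic covariance matrix of an ultrametric tree
#'
#' `A[i, j]` is the shared root-to-MRCA path length of leaves i and j
#' divided by the tree depth, so the diagonal is 1: the correlation
#' structure implied by Brownian trait evolution on the tree.
#'
#' @param tree ultrametric rooted `phylo`.
#' @param tolerance relative ultrametricity tolerance.
#' @return symmetric positive semi-definite matrix with unit diagonal,
#'   dimnames = leaf names.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' phyloCov(tr)["A", "B"]   # 0.5
#' @export
phyloCov <- function(tree, tolerance = 1e-6) {
  dev <- ultrametricDeviation(tree)
  if (dev$rel > tolerance)
    stop(sprintf("tree is not ultrametric (max deviation %.3g)", dev$abs))
  V <- ape::vcv(tree)
  A <- V / dev$depth
  diag(A) <- 1
  A
}

## profile log-likelihood machinery: V(h2) = sigma2 (h2 A + (1-h2) I),
## GLS beta and closed-form sigma2 at each h2 after rotating into A's
## eigenbasis
.pmmProfile <- function(yStar, XStar, ev) {
  n <- length(yStar)
  function(h2) {
    w <- h2 * ev + (1 - h2)
    w[w < 1e-12] <- 1e-12
    Xw <- XStar / w
    XtWX <- crossprod(XStar, Xw)
    XtWy <- crossprod(Xw, yStar)
    beta <- solve(XtWX, XtWy)
    r <- yStar - XStar %*% beta
    rss <- sum(r^2 / w)
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + sum(log(w)) + n)
    list(ll = ll, beta = drop(beta), sigma2 = sigma2, XtWX = XtWX, w = w)
  }
}

#' Fit a univariate phylogenetic mixed model by maximum likelihood
#'
#' Fits `y ~ Normal(X beta, V (h2 A + (1 - h2) I))` by profiling the
#' likelihood over the heritability `h2` on [0, 1] (generalized least
#' squares for beta and a closed-form variance at each h2, maximized by
#' bounded one-dimensional search, tolerance 1e-8). Fixed-effect 95%
#' intervals come from the GLS covariance at the optimum. With a tree
#' supplied, internal-node trait values are predicted as the GLS
#' intercept plus the BLUP of the phylogenetic random effect given the
#' tip data.
#'
#' @param y named numeric response per species.
#' @param X covariate matrix (rows = species); `NULL` fits an intercept
#'   only. An intercept column is added when absent.
#' @param A phylogenetic correlation matrix from [phyloCov()].
#' @param tree optional `phylo` matching `A`, enabling ancestral node
#'   prediction.
#' @return a [PMMFit-class]. When the profile likelihood is flat in h2
#'   (e.g. a star phylogeny, where `A` is the identity), the fit is
#'   flagged non-identifiable.
#' @export
fitPmm <- function(y, X = NULL, A, tree = NULL) {
  sp <- rownames(A)
  if (is.null(names(y))) stop("'y' must be named by species")
  if (!all(sp %in% names(y))) stop("species mismatch between y and A")
  y <- y[sp]
  n <- length(y)
  if (n < 10L) stop("need at least 10 species")
  if (is.null(X)) {
    X <- matrix(1, n, 1L, dimnames = list(sp, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    if (!is.null(rownames(X))) X <- X[sp, , drop = FALSE]
    if (!any(apply(X, 2L, function(c) all(c == c[1L] & c[1L] != 0))))
      X <- cbind(`(Intercept)` = 1, X)
  }
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  eig <- eigen(A, symmetric = TRUE)
  U <- eig$vectors
  yStar <- drop(crossprod(U, y))
  XStar <- crossprod(U, X)
  prof <- .pmmProfile(yStar, XStar, eig$values)

  llFun <- function(h2) prof(h2)$ll
  opt <- stats::optimize(llFun, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, 0, 1)
  lls <- vapply(cand, llFun, 1)
  h2 <- cand[which.max(lls)]
  fit <- prof(h2)

  grid <- vapply(seq(0, 1, by = 0.05), llFun, 1)
  identifiable <- (max(grid) - min(grid)) > 1e-6

  covB <- fit$sigma2 * solve(fit$XtWX)
  se <- sqrt(diag(covB))
  z <- stats::qnorm(0.975)
  beta <- data.frame(term = colnames(X), estimate = fit$beta, se = se,
                     lower = fit$beta - z * se,
                     upper = fit$beta + z * se,
                     stringsAsFactors = FALSE, row.names = NULL)
  sigma2p <- h2 * fit$sigma2
  sigma2e <- (1 - h2) * fit$sigma2

  ancestral <- numeric(0)
  if (!is.null(tree)) {
    icol <- match("(Intercept)", colnames(X))
    intercept <- if (!is.na(icol)) fit$beta[icol] else 0
    nd <- ape::node.depth.edgelength(tree)
    depth <- max(nd[seq_len(ape::Ntip(tree))])
    Mfull <- ape::mrca(tree, full = TRUE)
    nTip <- ape::Ntip(tree)
    tipIdx <- match(sp, tree$tip.label)
    resid <- y - drop(X %*% fit$beta)
    Vinv <- U %*% ((1 / fit$w) * t(U)) / fit$sigma2
    nodes <- nTip + seq_len(tree$Nnode)
    ancestral <- vapply(nodes, function(v) {
      cvec <- sigma2p * nd[Mfull[v, tipIdx]] / depth
      intercept + drop(cvec %*% Vinv %*% resid)
    }, 1)
    names(ancestral) <- if (!is.null(tree$node.label) &&
                            length(tree$node.label) == tree$Nnode)
      tree$node.label else paste0("node", nodes)
  }
  new("PMMFit", beta = beta, sigma2p = sigma2p, sigma2e = sigma2e,
      h2 = h2, loglik = fit$ll, ancestral = ancestral,
      identifiable = identifiable)
}

## negative log-likelihood of the bivariate model after rotation into
## A's eigenbasis: per species i, Sigma_i = ev_i P + R (2x2); beta is
## profiled out by GLS inside each evaluation
.bivNegLL <- function(par, yS, XS, ev) {
  P <- .sdcor2cov(par[1:3])
  R <- .sdcor2cov(par[4:6])
  n <- length(ev); p <- ncol(XS)
  S11 <- ev * P[1, 1] + R[1, 1]
  S22 <- ev * P[2, 2] + R[2, 2]
  S12 <- ev * P[1, 2] + R[1, 2]
  d <- S11 * S22 - S12^2
  if (any(!is.finite(d)) || any(d <= 1e-300)) return(1e10)
  W11 <- S22 / d; W22 <- S11 / d; W12 <- -S12 / d
  ## GLS for B (p x 2): block normal equations
  M <- rbind(cbind(crossprod(XS, W11 * XS), crossprod(XS, W12 * XS)),
             cbind(crossprod(XS, W12 * XS), crossprod(XS, W22 * XS)))
  v <- c(crossprod(XS, W11 * yS[, 1] + W12 * yS[, 2]),
         crossprod(XS, W12 * yS[, 1] + W22 * yS[, 2]))
  B <- tryCatch(matrix(solve(M, v), p, 2), error = function(e) NULL)
  if (is.null(B)) return(1e10)
  res <- yS - XS %*% B
  quad <- W11 * res[, 1]^2 + 2 * W12 * res[, 1] * res[, 2] +
    W22 * res[, 2]^2
  0.5 * (sum(log(d)) + sum(quad)) + n * log(2 * pi)
}

## (log sd1, log sd2, atanh rho) -> 2x2 covariance
.sdcor2cov <- function(p) {
  s1 <- exp(min(p[1], 15)); s2 <- exp(min(p[2], 15))
  r <- tanh(p[3])
  matrix(c(s1^2, r * s1 * s2, r * s1 * s2, s2^2), 2)
}

#' Fit a bivariate phylogenetic mixed model
#'
#' Maximum-likelihood fit of two species traits with covariance
#' `P %x% A + R %x% I`, parameterized through log standard deviations
#' and Fisher-transformed correlations. The phylogenetic correlation
#' `rho_phylo = P[1,2]/sqrt(P[1,1] P[2,2])` is returned with an
#' optional profile-likelihood 95% interval.
#'
#' @param y1,y2 named numeric traits per species.
#' @param X covariate matrix shared by both traits (`NULL` =
#'   intercepts).
#' @param A phylogenetic correlation matrix from [phyloCov()].
#' @param ci compute the profile-likelihood interval for `rho_phylo`
#'   (slower); default `TRUE`.
#' @param nRestarts bounded random restarts when the first optimization
#'   fails to improve.
#' @return a [BivariatePMMFit-class].
#' @export
fitBivariatePmm <- function(y1, y2, X = NULL, A, ci = TRUE,
                            nRestarts = 3L) {
  sp <- rownames(A)
  if (!all(sp %in% names(y1)) || !all(sp %in% names(y2)))
    stop("species mismatch between traits and A")
  y1 <- y1[sp]; y2 <- y2[sp]
  n <- length(sp)
  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(sp, "(Intercept)"))
  else {
    X <- as.matrix(X)
    if (!is.null(rownames(X))) X <- X[sp, , drop = FALSE]
    if (!any(apply(X, 2L, function(c) all(c == c[1L] & c[1L] != 0))))
      X <- cbind(`(Intercept)` = 1, X)
  }
  eig <- eigen(A, symmetric = TRUE)
  U <- eig$vectors
  yS <- cbind(drop(crossprod(U, y1)), drop(crossprod(U, y2)))
  XS <- crossprod(U, X)
  ev <- eig$values

  ## moment-based start from univariate fits
  f1 <- fitPmm(y1, NULL, A); f2 <- fitPmm(y2, NULL, A)
  start <- c(0.5 * log(max(f1@sigma2p, 1e-4)),
             0.5 * log(max(f2@sigma2p, 1e-4)),
             atanh(0.9 * stats::cor(y1, y2)),
             0.5 * log(max(f1@sigma2e, 1e-4)),
             0.5 * log(max(f2@sigma2e, 1e-4)), 0)
  obj <- function(p) .bivNegLL(p, yS, XS, ev)
  best <- stats::optim(start, obj, method = "L-BFGS-B",
                       lower = rep(c(-10, -10, -6), 2),
                       upper = rep(c(10, 10, 6), 2),
                       control = list(maxit = 500))
  for (k in seq_len(nRestarts)) {
    if (best$convergence == 0 && is.finite(best$value) &&
        best$value < 1e9) break
    jitter <- start + stats::rnorm(6, 0, 0.5 * k)
    cand <- tryCatch(stats::optim(jitter, obj, method = "L-BFGS-B",
                                  lower = rep(c(-10, -10, -6), 2),
                                  upper = rep(c(10, 10, 6), 2),
                                  control = list(maxit = 500)),
                     error = function(e) NULL)
    if (!is.null(cand) && cand$value < best$value) best <- cand
  }
  if (!is.finite(best$value) || best$value >= 1e9)
    stop("bivariate fit failed to converge; best parameters: ",
         paste(signif(best$par, 3), collapse = ", "))
  P <- .sdcor2cov(best$par[1:3])
  R <- .sdcor2cov(best$par[4:6])
  rho <- tanh(best$par[3])
  ll <- -best$value

  rhoLo <- rhoHi <- NA_real_
  if (ci) {
    profNeg <- function(z) {
      o <- stats::optim(best$par[-3], function(q)
        .bivNegLL(c(q[1:2], z, q[3:5]), yS, XS, ev),
        method = "L-BFGS-B", lower = rep(c(-10, -10, -6), 2)[-3],
        upper = rep(c(10, 10, 6), 2)[-3], control = list(maxit = 300))
      o$value
    }
    cut <- best$value + stats::qchisq(0.95, 1) / 2
    bound <- function(dir) {
      lo <- best$par[3]; hi <- dir * 6
      if (profNeg(hi) < cut) return(tanh(hi))
      for (it in 1:25) {
        mid <- (lo + hi) / 2
        if (profNeg(mid) < cut) lo <- mid else hi <- mid
      }
      tanh((lo + hi) / 2)
    }
    rhoLo <- min(bound(-1), rho)
    rhoHi <- max(bound(1), rho)
  }
  new("BivariatePMMFit", P = P, R = R, rhoPhylo = rho, rhoLower = rhoLo,
      rhoUpper = rhoHi, loglik = ll,
      converged = best$convergence == 0)
}
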