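#' One-year transition probabilities of a CTMC generator
#'
#' For a continuous-time Markov chain with intensity (generator) matrix Q,
#' the transition probability matrix over a duration t is the matrix
#' exponential P(t) = exp(Qt); rows of P are probability distributions.
#'
#' @param q 3x3 generator: non-negative off-diagonals, rows summing to 0.
#' @param t duration in years (default 1).
#' @return row-stochastic matrix exp(Qt).
#' @export
#' @examples
#' q <- rbind(c(-0.2, 0.15, 0.05), c(0.6, -0.8, 0.2), c(0.5, 0.2, -0.7))
#' rowSums(transition_probability(q))  # all 1
transition_probability <- function(q, t = 1) {
  check_generator(q)
  P <- as.matrix(Matrix::expm(q * t))
  dimnames(P) <- dimnames(q)
  P
}

check_generator <- function(q) {
  if (!is.matrix(q) || nrow(q) != ncol(q))
    stop("generator must be a square matrix")
  off <- q[row(q) != col(q)]
  if (any(off < 0)) stop("generator has negative off-diagonal intensities")
  if (any(abs(rowSums(q)) > 1e-8)) stop("generator rows must sum to zero")
  invisible(q)
}

states3 <- c("NC", "IN", "DI")

# panel (n x 5 matrix of states) -> list of 4 per-piece 3x3 count matrices
panel_counts <- function(panel) {
  panel <- as.matrix(panel)
  if (ncol(panel) < 2) stop("panel needs at least two annual observations")
  lapply(seq_len(ncol(panel) - 1), function(k)
    unclass(table(factor(panel[, k], levels = states3),
                  factor(panel[, k + 1], levels = states3))))
}

# build Q from the 6 log-intensities of one piece
q_from_theta <- function(theta) {
  q <- matrix(0, 3, 3, dimnames = list(states3, states3))
  q[row(q) != col(q)] <- exp(theta)  # column-major over off-diagonals
  diag(q) <- -rowSums(q)
  q
}

theta_from_q <- function(q) log(pmax(q[row(q) != col(q)], 1e-12))

# principal matrix logarithm via the eigendecomposition; NULL when no real
# logarithm exists (negative or complex-modulus-unstable eigenvalues)
logm3 <- function(P) {
  e <- tryCatch(eigen(P), error = function(e) NULL)
  if (is.null(e)) return(NULL)
  if (any(Mod(e$values) < 1e-12) || any(Re(as.complex(e$values)) <= 0 &
                                        abs(Im(as.complex(e$values))) < 1e-12))
    return(NULL)
  L <- tryCatch(Re(e$vectors %*% diag(log(as.complex(e$values))) %*%
                     solve(e$vectors)), error = function(e) NULL)
  if (is.null(L) || any(!is.finite(L))) return(NULL)
  if (max(abs(as.matrix(Matrix::expm(L)) - P)) > 1e-8) return(NULL)
  L
}

# negative log-likelihood of one piece: -sum n_ij log P_ij(Q(theta))
piece_nll <- function(theta, counts) {
  P <- as.matrix(Matrix::expm(q_from_theta(theta)))
  if (any(P[counts > 0] <= 0)) return(Inf)
  -sum(counts[counts > 0] * log(P[counts > 0]))
}

#' Log-likelihood of annual panel data under piecewise-constant intensities
#'
#' States are observed only at the annual assessment points; the likelihood
#' of each observed one-year transition is the corresponding entry of the
#' matrix exponential of that interval's generator (panel-data likelihood;
#' transitions between observations are unobserved). An observed
#' transition of probability zero yields `-Inf`, reported rather than
#' raised.
#'
#' @param panel matrix (patients x years) of states `"NC"/"IN"/"DI"`.
#' @param generators list of one generator per inter-observation interval
#'   (`ncol(panel) - 1` pieces).
#' @return the log-likelihood (possibly `-Inf`).
#' @export
panel_loglik <- function(panel, generators) {
  counts <- panel_counts(panel)
  if (length(generators) != length(counts))
    stop(sprintf("need %d generator pieces, got %d",
                 length(counts), length(generators)))
  ll <- 0
  for (k in seq_along(counts)) {
    check_generator(generators[[k]])
    P <- as.matrix(Matrix::expm(generators[[k]]))
    n <- counts[[k]]
    if (any(n[P <= 0] > 0)) return(-Inf)
    ll <- ll + sum(n[n > 0] * log(P[n > 0]))
  }
  ll
}

#' Fit the piecewise-constant multi-state Markov model
#'
#' Maximum-likelihood fit of a three-state (no change / intensification /
#' de-intensification) continuous-time Markov model to annual panel data,
#' with a separate generator for every one-year interval (piecewise
#' constant intensities; each observation gap is treated as exactly one
#' year). Intensities are optimized on the log scale, which enforces
#' positivity; each piece is initialized from the matrix logarithm of its
#' empirical transition matrix when that is a valid generator (in which
#' case the empirical matrix is itself the MLE, since the per-piece model
#' is saturated), and from continuity-corrected crude rates otherwise.
#' Element-wise 95% confidence intervals for the one-year transition
#' probabilities come from a seeded parametric bootstrap over the
#' asymptotic normal of the log-intensities, propagated through the matrix
#' exponential.
#'
#' @param panel matrix or data.frame (patients x years) of annual states.
#' @param boot_draws bootstrap draws for the CIs (default 500; 0 disables).
#' @param seed seed for the bootstrap draws.
#' @param reltol optimizer convergence tolerance (default 1e-12).
#' @param conf_level confidence level (default 0.95).
#' @return object of class `msm_pw`: per-piece generators, one-year
#'   probability matrices with CIs, transition counts, log-likelihood and a
#'   convergence report. Methods: `print`, `summary`, `coef`, `plot`,
#'   `simulate`, `residuals`, `logLik`.
#' @export
fit_msm <- function(panel, boot_draws = 500, seed = 1L, reltol = 1e-12,
                    conf_level = 0.95) {
  panel <- as.matrix(panel)
  counts <- panel_counts(panel)
  seen <- table(factor(panel, levels = states3))
  if (any(seen == 0))
    warning("state(s) never observed: ",
            paste(names(seen)[seen == 0], collapse = ", "),
            "; the corresponding intensities are unidentified")
  pieces <- vector("list", length(counts))
  for (k in seq_along(counts)) {
    n <- counts[[k]]
    rowtot <- rowSums(n)
    Phat <- n / ifelse(rowtot > 0, rowtot, 1)
    diag(Phat)[rowtot == 0] <- 1  # unobserved row: stay put
    init <- NULL
    L <- logm3(Phat)
    if (!is.null(L)) {
      off <- L[row(L) != col(L)]
      if (all(off > -1e-8)) {
        L[row(L) != col(L)] <- pmax(off, 1e-10)
        diag(L) <- 0; diag(L) <- -rowSums(L)
        init <- theta_from_q(L)
      }
    }
    if (is.null(init)) {
      crude <- (n + 0.5) / (rowtot + 1.5)
      q0 <- crude; diag(q0) <- 0
      init <- log(pmax(q0[row(q0) != col(q0)], 1e-6))
    }
    opt <- stats::optim(init, piece_nll, counts = n, method = "BFGS",
                        control = list(maxit = 500, reltol = reltol),
                        hessian = boot_draws > 0)
    grad <- num_grad(function(th) piece_nll(th, n), opt$par)
    pieces[[k]] <- list(theta = opt$par, q = q_from_theta(opt$par),
                        counts = n, nll = opt$value,
                        converged = opt$convergence == 0,
                        grad_norm = max(abs(grad)),
                        hessian = if (boot_draws > 0) opt$hessian else NULL)
  }
  prob <- lapply(seq_along(pieces), function(k) {
    pc <- pieces[[k]]
    P <- as.matrix(Matrix::expm(pc$q))
    dimnames(P) <- list(states3, states3)
    ci <- boot_ci(pc, boot_draws, seed + k, conf_level)
    list(p = P, ci_low = ci$lo, ci_high = ci$hi)
  })
  first <- table(factor(panel[, 1], levels = states3))
  structure(list(pieces = pieces, prob = prob,
                 loglik = -sum(vapply(pieces, `[[`, numeric(1), "nll")),
                 first_dist = as.numeric(first) / sum(first),
                 n = nrow(panel), n_years = ncol(panel),
                 boot_draws = boot_draws, seed = seed,
                 conf_level = conf_level,
                 convergence = data.frame(
                   piece = seq_along(pieces),
                   converged = vapply(pieces, `[[`, logical(1), "converged"),
                   grad_norm = vapply(pieces, `[[`, numeric(1), "grad_norm"))),
            class = "msm_pw")
}

num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# parametric bootstrap CI for one piece's 1-year probabilities
boot_ci <- function(piece, B, seed, conf_level) {
  P <- as.matrix(Matrix::expm(piece$q))
  if (B <= 0 || is.null(piece$hessian))
    return(list(lo = matrix(NA_real_, 3, 3), hi = matrix(NA_real_, 3, 3)))
  H <- piece$hessian
  V <- tryCatch(solve(H + diag(1e-8, nrow(H))), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V)))
    return(list(lo = matrix(NA_real_, 3, 3), hi = matrix(NA_real_, 3, 3)))
  ev <- eigen(V, symmetric = TRUE)
  R <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  set.seed(seed)
  Z <- matrix(stats::rnorm(B * length(piece$theta)), B)
  draws <- array(NA_real_, c(3, 3, B))
  for (b in seq_len(B)) {
    th <- piece$theta + as.numeric(R %*% Z[b, ])
    # clamp weakly identified log-intensities (near-empty rows) so the
    # matrix exponential stays finite; e^6 / year is far beyond any
    # annual-panel-compatible intensity
    th <- pmin(pmax(th, -30), 6)
    Pb <- as.matrix(Matrix::expm(q_from_theta(th)))
    if (all(is.finite(Pb))) draws[, , b] <- Pb
  }
  a <- (1 - conf_level) / 2
  lo <- apply(draws, c(1, 2), stats::quantile, probs = a, names = FALSE,
              na.rm = TRUE)
  hi <- apply(draws, c(1, 2), stats::quantile, probs = 1 - a, names = FALSE,
              na.rm = TRUE)
  # intervals always contain the point estimate
  list(lo = pmin(lo, P), hi = pmax(hi, P))
}

#' Simulate annual panel data from piecewise generators
#'
#' Draws the first-year state from `init` and evolves it through the
#' one-year transition matrices exp(Q_k) of the supplied generator pieces.
#'
#' @param n number of patients.
#' @param generators list of generator matrices (one per interval).
#' @param init probability vector over (NC, IN, DI) for the first year.
#' @param seed RNG seed.
#' @return character matrix `n x (length(generators) + 1)`.
#' @export
simulate_panel <- function(n, generators, init = c(0.876, 0.077, 0.047),
                           seed = 1L) {
  set.seed(seed)
  Ps <- lapply(generators, function(q) as.matrix(Matrix::expm(q)))
  ny <- length(generators) + 1
  panel <- matrix(NA_character_, n, ny)
  panel[, 1] <- sample(states3, n, replace = TRUE, prob = init)
  for (k in seq_along(Ps)) {
    for (s in 1:3) {
      rows <- panel[, k] == states3[s]
      if (any(rows))
        panel[rows, k + 1] <- sample(states3, sum(rows), replace = TRUE,
                                     prob = Ps[[k]][s, ])
    }
  }
  panel
}

#' @export
simulate.msm_pw <- function(object, nsim = 1, seed = NULL, n = object$n,
                            init = object$first_dist, ...) {
  if (is.null(seed)) seed <- 1L
  simulate_panel(n, lapply(object$pieces, `[[`, "q"), init = init, seed = seed)
}

#' Observed versus expected transition counts
#'
#' Model-fit check: expected count for cell (i, j) of piece k is the
#' observed row-i marginal at the start of the piece times the fitted
#' one-year transition probability; Pearson residuals accompany the table.
#'
#' @param fit an `msm_pw` object.
#' @return data.frame with piece, from, to, observed, expected and Pearson
#'   residual; expected counts row-sum to the observed row marginals.
#' @export
goodness_of_fit <- function(fit) {
  out <- list()
  for (k in seq_along(fit$pieces)) {
    n <- fit$pieces[[k]]$counts
    P <- fit$prob[[k]]$p
    E <- rowSums(n) * P
    res <- (n - E) / sqrt(ifelse(E > 0, E, NA_real_))
    out[[k]] <- data.frame(piece = k,
                           from = rep(states3, 3),
                           to = rep(states3, each = 3),
                           observed = as.integer(n),
                           expected = as.numeric(E),
                           pearson = as.numeric(res))
  }
  do.call(rbind, out)
}

#' @export
residuals.msm_pw <- function(object, ...) goodness_of_fit(object)$pearson

#' @export
logLik.msm_pw <- function(object, ...) {
  structure(object$loglik, df = 6 * length(object$pieces), class = "logLik")
}

#' @export
coef.msm_pw <- function(object, ...) {
  do.call(rbind, lapply(seq_along(object$pieces), function(k) {
    q <- object$pieces[[k]]$q
    data.frame(piece = k, from = rep(states3, 3), to = rep(states3, each = 3),
               intensity = as.numeric(q))
  }))
}

#' @export
print.msm_pw <- function(x, digits = 3, ...) {
  cat(sprintf(paste0("Piecewise-constant 3-state Markov model ",
                     "(%d patients, %d annual observations)\n"),
              x$n, x$n_years))
  cat(sprintf("log-likelihood: %.2f\n", x$loglik))
  for (k in seq_along(x$prob)) {
    cat(sprintf("-- interval %d -> %d: 1-year transition probabilities --\n",
                k, k + 1))
    print(round(x$prob[[k]]$p, digits))
  }
  invisible(x)
}

#' @export
summary.msm_pw <- function(object, ...) {
  tabs <- lapply(seq_along(object$prob), function(k) {
    p <- object$prob[[k]]
    data.frame(piece = k, from = rep(states3, 3), to = rep(states3, each = 3),
               prob = as.numeric(p$p), ci_low = as.numeric(p$ci_low),
               ci_high = as.numeric(p$ci_high))
  })
  out <- list(table = do.call(rbind, tabs), loglik = object$loglik,
              convergence = object$convergence, n = object$n)
  class(out) <- "summary.msm_pw"
  out
}

#' @export
print.summary.msm_pw <- function(x, ...) {
  cat(sprintf("1-year transition probabilities with %s CIs (n = %d)\n",
              "bootstrap", x$n))
  print(x$table, digits = 3, row.names = FALSE)
  cat(sprintf("log-likelihood %.2f; max gradient norm %.2e\n",
              x$loglik, max(x$convergence$grad_norm)))
  invisible(x)
}

#' Network plot of fitted one-year transition probabilities
#'
#' Draws the three states as nodes with directed edges labelled by the
#' fitted one-year transition probabilities of one interval (self-loops
#' shown as node labels).
#'
#' @param x an `msm_pw` fit.
#' @param piece which interval to draw (default 1).
#' @param ... unused.
#' @export
plot.msm_pw <- function(x, piece = 1, ...) {
  P <- x$prob[[piece]]$p
  xy <- rbind(c(0, 1), c(-0.87, -0.5), c(0.87, -0.5))
  graphics::plot(NA, xlim = c(-1.4, 1.4), ylim = c(-1.1, 1.5), axes = FALSE,
                 xlab = "", ylab = "",
                 main = sprintf("1-year transition probabilities, interval %d",
                                piece))
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    v <- xy[j, ] - xy[i, ]
    v <- v / sqrt(sum(v^2))
    off <- c(-v[2], v[1]) * 0.06
    a <- xy[i, ] + v * 0.25 + off; b <- xy[j, ] - v * 0.25 + off
    graphics::arrows(a[1], a[2], b[1], b[2], length = 0.08,
                     col = c("forestgreen", "firebrick", "steelblue")[i])
    mid <- (a + b) / 2 + off * 2
    graphics::text(mid[1], mid[2], sprintf("%.2f", P[i, j]), cex = 0.8)
  }
  for (i in 1:3) {
    graphics::symbols(xy[i, 1], xy[i, 2], circles = 0.18, inches = FALSE,
                      add = TRUE, bg = "grey95")
    graphics::text(xy[i, 1], xy[i, 2],
                   sprintf("%s\n%.2f", states3[i], P[i, i]), cex = 0.9)
  }
  invisible(x)
}
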