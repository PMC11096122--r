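#' Prior hyperparameters for the MityBayes model
#'
#' @param alpha Dirichlet concentration on the clone fractions pi
#'   (default 1, flat).
#' @param a,b Beta hyperparameters on each clone-specific heteroplasmy
#'   P_kv (default 1, 1, flat).
#' @param fixedPi optional length-K simplex; when supplied, pi is held
#'   fixed at this value instead of being inferred.
#' @return list of validated hyperparameters.
#' @export
mbPriors <- function(alpha = 1, a = 1, b = 1, fixedPi = NULL) {
  if (alpha <= 0 || a <= 0 || b <= 0)
    stop("all hyperparameters must be > 0")
  if (!is.null(fixedPi)) {
    if (abs(sum(fixedPi) - 1) > 1e-9 || any(fixedPi < 0))
      stop("'fixedPi' must be a probability simplex")
  }
  list(alpha = alpha, a = a, b = b, fixedPi = fixedPi)
}

# log-likelihood matrix ll[c, k] = sum_v log Binom(alt_cv | total_cv, P_kv)
mbLogLik <- function(alt, total, P) {
  C <- nrow(alt); V <- ncol(alt); K <- nrow(P)
  ll <- matrix(0, C, K)
  for (k in seq_len(K)) {
    pm <- matrix(P[k, ], C, V, byrow = TRUE)
    ll[, k] <- rowSums(dbinom(alt, total, pm, log = TRUE))
  }
  ll
}

# MAP objective: marginal log-likelihood + log prior densities (up to
# constants independent of the parameters)
mbObjective <- function(alt, total, pi, P, priors) {
  ll <- mbLogLik(alt, total, P)
  s <- sweep(ll, 2L, log(pi), "+")
  obj <- sum(rowLogSumExp(s))
  if (is.null(priors$fixedPi))
    obj <- obj + (priors$alpha - 1) * sum(log(pi))
  obj + sum((priors$a - 1) * log(P) + (priors$b - 1) * log1p(-P))
}

mbResponsibilities <- function(alt, total, pi, P) {
  s <- sweep(mbLogLik(alt, total, P), 2L, log(pi), "+")
  g <- exp(s - rowLogSumExp(s))
  g / rowSums(g)
}

# one EM run from a given initialization
mbEm <- function(alt, total, K, priors, relTol, maxIter, pi0, P0) {
  pi <- pi0; P <- clipProb(P0)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    gamma <- mbResponsibilities(alt, total, pi, P)
    # M step (MAP)
    if (is.null(priors$fixedPi)) {
      piNew <- colSums(gamma) + priors$alpha - 1
      piNew <- pmax(piNew, 1e-12)
      pi <- piNew / sum(piNew)
    }
    num <- crossprod(gamma, alt) + priors$a - 1       # K x V
    den <- crossprod(gamma, total) + priors$a + priors$b - 2
    P <- clipProb(ifelse(den > 0, num / pmax(den, 1e-12), 0.5))
    obj <- mbObjective(alt, total, pi, P, priors)
    if (!is.finite(obj))
      stop("non-finite objective at iteration ", it)
    trace <- c(trace, obj)
    if (it > 1L) {
      rel <- abs(obj - trace[it - 1L]) / (abs(trace[it - 1L]) + 1e-12)
      if (rel < relTol) { converged <- TRUE; break }
    }
  }
  gamma <- mbResponsibilities(alt, total, pi, P)
  list(pi = pi, P = P, gamma = gamma, trace = trace, converged = converged)
}

# gradient backend: ascent with backtracking line search on the same MAP
# objective, in unconstrained coordinates (softmax pi, logit P). The
# backtracking step keeps the objective monotone; `lr` is the initial
# step size.
mbGradient <- function(alt, total, K, priors, relTol, maxIter, pi0, P0,
                       lr = 0.1) {
  V <- ncol(alt); C <- nrow(alt)
  fixedPi <- priors$fixedPi
  u <- log(pmax(pi0, 1e-8)); u <- u - u[1L]
  Tm <- stats::qlogis(clipProb(P0))
  unpack <- function(u, Tm) {
    pi <- if (is.null(fixedPi)) { e <- exp(u - max(u)); e / sum(e) }
          else fixedPi
    list(pi = pi, P = clipProb(stats::plogis(Tm)))
  }
  objAt <- function(u, Tm) {
    par <- unpack(u, Tm)
    mbObjective(alt, total, par$pi, par$P, priors)
  }
  gradAt <- function(u, Tm) {
    par <- unpack(u, Tm)
    gamma <- mbResponsibilities(alt, total, par$pi, par$P)
    gU <- if (is.null(fixedPi)) {
      colSums(gamma) - par$pi * C +
        (priors$alpha - 1) * (1 - K * par$pi)
    } else rep(0, K)
    gT <- crossprod(gamma, alt) - crossprod(gamma, total) * par$P +
      (priors$a - 1) * (1 - par$P) - (priors$b - 1) * par$P
    list(gU = gU, gT = gT)
  }
  trace <- numeric(0)
  obj <- objAt(u, Tm)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    g <- gradAt(u, Tm)
    step <- lr
    improved <- FALSE
    for (ls in 1:30) {
      u2 <- u + step * g$gU
      T2 <- Tm + step * g$gT
      obj2 <- objAt(u2, T2)
      if (is.finite(obj2) && obj2 >= obj) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; trace <- c(trace, obj); break }
    u <- u2; Tm <- T2
    rel <- abs(obj2 - obj) / (abs(obj) + 1e-12)
    obj <- obj2
    trace <- c(trace, obj)
    if (rel < relTol) { converged <- TRUE; break }
  }
  par <- unpack(u, Tm)
  gamma <- mbResponsibilities(alt, total, par$pi, par$P)
  list(pi = par$pi, P = par$P, gamma = gamma, trace = trace,
       converged = converged)
}

#' Fit the MityBayes clonal-assignment model
#'
#' Cells are assigned to K clones from mtDNA variant read counts: the
#' alternate read count of variant v in cell c is Binomial(total_cv,
#' P_kv) given clone k, with clone fractions pi. The fit maximizes the
#' MAP objective
#' \deqn{\sum_c \log \sum_k \pi_k \prod_v \mathrm{Binom}(a_{cv} \mid
#'   n_{cv}, P_{kv}) + \log \mathrm{prior}}
#' over (pi, P), marginalizing the assignments; posterior assignment
#' probabilities gamma are the responsibilities at the optimum. The
#' default backend is EM (monotone in the objective); a gradient backend
#' (ascent with backtracking from initial step `lr` in softmax/logit
#' coordinates) optimizes the identical objective and must agree within
#' tolerance. Multiple restarts are run from seeded initializations and
#' the best objective is kept; results are deterministic given `seed`.
#'
#' @param alt,total cells x variants matrices of alternate and total read
#'   counts (alt <= total elementwise).
#' @param K number of clones (1 <= K <= cells).
#' @param priors hyperparameters from [mbPriors()].
#' @param backend "em" (default) or "gradient".
#' @param lr initial step size of the gradient backend (default 0.1).
#' @param relTol relative objective change declaring convergence
#'   (default 1e-5).
#' @param maxIter iteration cap per restart (default 500).
#' @param nRestarts restarts with distinct seeded initializations
#'   (default 8); the first uses a k-means warm start on the heteroplasmy
#'   matrix.
#' @param seed master seed; restart seeds are derived from it.
#' @return a [CloneModel-class].
#' @examples
#' alt <- rbind(c(10, 0), c(0, 10)); total <- matrix(10, 2, 2)
#' fitMityBayes(alt, total, K = 2, nRestarts = 2, seed = 1)
#' @export
fitMityBayes <- function(alt, total, K, priors = mbPriors(),
                         backend = c("em", "gradient"), lr = 0.1,
                         relTol = 1e-5, maxIter = 500L, nRestarts = 8L,
                         seed = 1L) {
  backend <- match.arg(backend)
  alt <- as.matrix(alt); total <- as.matrix(total)
  if (any(alt > total)) stop("alt counts exceed total counts")
  if (any(alt < 0 | total < 0)) stop("negative counts are invalid")
  C <- nrow(alt); V <- ncol(alt)
  if (K < 1L) stop("K must be >= 1")
  if (K > C) stop("K exceeds the number of cells")

  pooled <- colSums(alt) / pmax(colSums(total), 1)
  set.seed(deriveSeed(seed, "mitybayes-restarts"))
  restartSeeds <- sample.int(2147483646L, nRestarts)

  best <- NULL
  bestObj <- -Inf
  for (r in seq_len(nRestarts)) {
    set.seed(restartSeeds[r])
    init <- mbInit(alt, total, K, pooled, warmStart = (r == 1L))
    fit <- if (backend == "em") {
      mbEm(alt, total, K, priors, relTol, maxIter, init$pi, init$P)
    } else {
      mbGradient(alt, total, K, priors, relTol, maxIter, init$pi, init$P,
                 lr = lr)
    }
    obj <- tail2(fit$trace)
    if (is.finite(obj) && obj > bestObj) { bestObj <- obj; best <- fit }
  }

  model <- new("CloneModel",
    K = as.integer(K), pi = best$pi, P = best$P, gamma = best$gamma,
    contribution = numeric(V), elboTrace = best$trace,
    converged = best$converged, backend = backend,
    seed = as.integer(seed), alt = alt, total = total)
  model@contribution <- variantContribution(model)
  model
}

# seeded initialization: k-means warm start on the observed heteroplasmy
# (first restart) or a random hard partition otherwise
mbInit <- function(alt, total, K, pooled, warmStart = FALSE) {
  C <- nrow(alt); V <- ncol(alt)
  het <- ifelse(total > 0, alt / total,
                matrix(pooled, C, V, byrow = TRUE))
  z <- NULL
  if (warmStart && K > 1L && C > K) {
    km <- tryCatch(
      kmeans(het, centers = K, nstart = 1L, iter.max = 20L),
      error = function(e) NULL)
    if (!is.null(km)) z <- km$cluster
  }
  if (is.null(z))
    z <- c(seq_len(K), sample.int(K, C - K, replace = TRUE))[
      if (K > 1L) sample.int(C) else seq_len(C)]
  P <- matrix(NA_real_, K, V)
  for (k in seq_len(K)) {
    sel <- z == k
    P[k, ] <- (colSums(alt[sel, , drop = FALSE]) + 0.5) /
      (colSums(total[sel, , drop = FALSE]) + 1)
  }
  P <- clipProb(P + matrix(runif(K * V, -0.02, 0.02), K, V))
  pi <- tabulate(z, K) + 1
  list(pi = pi / sum(pi), P = P)
}

#' Assign cells to clones from a fitted model
#'
#' Labels each cell by its maximum-probability clone when that
#' probability reaches `minProb`, otherwise "unassigned". Ties go to the
#' lowest clone index.
#'
#' @param model a [CloneModel-class].
#' @param minProb minimum assignment probability (default 0.9).
#' @return character vector: "1".."K" or "unassigned".
#' @export
assignClones <- function(model, minProb = 0.9) {
  g <- model@gamma
  k <- max.col(g, ties.method = "first")
  mx <- g[cbind(seq_len(nrow(g)), k)]
  ifelse(mx >= minProb, as.character(k), "unassigned")
}

#' Per-variant contribution to the clone assignment
#'
#' How much each variant's clone-specific heteroplasmy improves the fit
#' over a clone-free (pooled heteroplasmy) model, averaged over the
#' posterior assignments:
#' \deqn{w_v \propto \sum_c \sum_k \gamma_{ck}
#'   [\log \mathrm{Binom}(a_{cv} \mid n_{cv}, P_{kv}) -
#'    \log \mathrm{Binom}(a_{cv} \mid n_{cv}, \bar p_v)]}
#' min-max rescaled to [0,1]. Clone-discriminating variants score high;
#' variants with identical heteroplasmy across clones score 0.
#'
#' @param model a [CloneModel-class].
#' @return numeric weight per variant in [0,1].
#' @export
variantContribution <- function(model) {
  alt <- model@alt; total <- model@total
  gamma <- model@gamma; P <- model@P
  V <- ncol(alt)
  pooled <- clipProb(colSums(alt) / pmax(colSums(total), 1))
  raw <- numeric(V)
  for (v in seq_len(V)) {
    llPool <- dbinom(alt[, v], total[, v], pooled[v], log = TRUE)
    sep <- 0
    for (k in seq_len(model@K)) {
      llK <- dbinom(alt[, v], total[, v], P[k, v], log = TRUE)
      sep <- sep + sum(gamma[, k] * (llK - llPool))
    }
    raw[v] <- sep
  }
  rng <- max(raw) - min(raw)
  if (rng < 1e-12) {
    return(rep(if (max(abs(raw)) > 1e-8) 1 else 0, V))
  }
  (raw - min(raw)) / rng
}

#' Choose the number of clones by penalized objective
#'
#' Fits each candidate K with restarts and reports a BIC-style penalized
#' objective, -2 x objective + nParams x log(cells), with nParams =
#' (K - 1) + K x V. The minimizer is chosen (ties to the smaller K); the
#' full table is returned so the choice can be overridden.
#'
#' @param alt,total count matrices as in [fitMityBayes()].
#' @param Kgrid candidate clone counts (default 1:5, capped at the cell
#'   count).
#' @param priors,nRestarts,seed,... passed to [fitMityBayes()].
#' @return list(K = chosen, table = data.frame(K, objective, n_params,
#'   bic)).
#' @export
selectK <- function(alt, total, Kgrid = 1:5, priors = mbPriors(),
                    nRestarts = 4L, seed = 1L, ...) {
  if (!length(Kgrid)) stop("'Kgrid' must be nonempty")
  Kgrid <- sort(unique(as.integer(Kgrid)))
  Kgrid <- Kgrid[Kgrid <= nrow(as.matrix(alt))]
  C <- nrow(as.matrix(alt)); V <- ncol(as.matrix(alt))
  rows <- lapply(Kgrid, function(K) {
    fit <- fitMityBayes(alt, total, K, priors = priors,
                        nRestarts = nRestarts,
                        seed = deriveSeed(seed, paste0("selectK", K)), ...)
    obj <- tail2(fit@elboTrace)
    nPar <- (K - 1) + K * V
    data.frame(K = K, objective = obj, n_params = nPar,
               bic = -2 * obj + nPar * log(C))
  })
  tab <- do.call(rbind, rows)
  list(K = tab$K[which.min(tab$bic)], table = tab)
}
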