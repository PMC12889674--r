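#' Fit a multivariate Bernoulli-emission hidden Markov model
#'
#' Maximum-likelihood fitting (Baum-Welch EM) of a ChromHMM-style chromatin
#' state model to a binarized mark matrix. Each genomic bin emits an M-vector
#' of conditionally independent Bernoulli mark calls given its hidden state;
#' chromosomes are treated as independent sequences, each restarted from the
#' initial distribution. All recursions run in log space.
#'
#' Initialization follows a quantile heuristic: bins are split into
#' `n_states` groups by their per-bin mark count, group-wise mark frequencies
#' (plus a small seeded jitter) seed the emissions, the transition matrix
#' starts sticky (0.9 on the diagonal), and the initial distribution uniform.
#' `n_restarts` independently jittered starts are fitted and the best
#' log-likelihood kept, which tames EM local optima.
#'
#' @param data a [binarized_matrix()].
#' @param n_states number of hidden states K.
#' @param seed integer seed controlling the jittered restarts.
#' @param tol EM stops when the log-likelihood gain drops below this
#'   (default 1e-3).
#' @param max_iter iteration cap per restart (default 200).
#' @param n_restarts jittered initializations (default 3).
#' @return an object of class `bhmm` with components `initial`,
#'   `transitions`, `emissions` (states x marks, clamped to
#'   \[1e-6, 1-1e-6\]), `train_log` (per-iteration log-likelihoods of the
#'   winning restart, non-decreasing) and `loglik`.
#' @seealso [predict.bhmm()] for Viterbi segmentation,
#'   [recompute_emissions()], [simulate.bhmm()].
#' @export
hmm_fit <- function(data, n_states, seed = 1L, tol = 1e-3, max_iter = 200L,
                    n_restarts = 3L) {
  stopifnot(inherits(data, "binarized_matrix"))
  K <- as.integer(n_states)
  if (K < 1L) stop("n_states must be >= 1")
  V <- data$values
  if (K > nrow(V)) stop("n_states exceeds the number of bins")
  seq_idx <- chrom_row_ranges(data$grid)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- hmm_init(V, K, substream(seed, 100L + r))
    fit <- baum_welch(V, seq_idx, init, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  structure(
    list(n_states = K, mark_names = data$mark_names,
         initial = best$pi, transitions = best$A, emissions = best$E,
         state_names = as.character(seq_len(K)),
         train_log = best$train_log, loglik = best$loglik,
         n_bins = nrow(V), cell_type = data$cell_type,
         call = match.call()),
    class = "bhmm")
}

# row index ranges of each chromosome in the flat bin vector
chrom_row_ranges <- function(grid) {
  offs <- grid_offsets(grid)
  lapply(seq_along(grid$n_bins), function(i)
    offs[i] + seq_len(grid$n_bins[i]))
}

hmm_init <- function(V, K, jitter_seed) {
  M <- ncol(V)
  with_seed(jitter_seed, {
    cnt <- rowSums(V)
    grp <- if (K == 1L) rep(1L, nrow(V))
           else as.integer(cut(rank(cnt, ties.method = "first"),
                               breaks = K, labels = FALSE))
    E <- matrix(0.5, K, M)
    for (s in seq_len(K)) {
      rows <- which(grp == s)
      if (length(rows)) E[s, ] <- colMeans(V[rows, , drop = FALSE])
    }
    E <- clamp01(E + matrix(runif(K * M, -0.05, 0.05), K, M))
    A <- matrix(if (K > 1) 0.1 / (K - 1) else 0, K, K)
    diag(A) <- if (K > 1) 0.9 else 1
    list(pi = rep(1 / K, K), A = A, E = E)
  })
}

clamp01 <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

# log emission probabilities of every bin under every state: T x K
bernoulli_logB <- function(V, E) {
  V %*% t(log(E)) + (1 - V) %*% t(log1p(-E))
}

baum_welch <- function(V, seq_idx, init, tol, max_iter) {
  K <- nrow(init$E)
  pi <- init$pi; A <- init$A; E <- clamp01(init$E)
  train_log <- numeric(0)
  prev <- -Inf
  for (iter in seq_len(max_iter)) {
    logB <- bernoulli_logB(V, E)
    logA <- log(A); logpi <- log(pi)
    ll <- 0
    pi_acc <- numeric(K)
    xi_acc <- matrix(0, K, K)
    em_num <- matrix(0, K, ncol(V))
    em_den <- numeric(K)
    for (rows in seq_idx) {
      fb <- .fb_pass(logpi, logA, logB[rows, , drop = FALSE])
      ll <- ll + fb$loglik
      pi_acc <- pi_acc + fb$gamma[1, ]
      xi_acc <- xi_acc + fb$xi
      em_num <- em_num + t(fb$gamma) %*% V[rows, , drop = FALSE]
      em_den <- em_den + colSums(fb$gamma)
    }
    train_log <- c(train_log, ll)
    if (ll - prev < tol && iter > 1L) break
    prev <- ll
    pi <- pi_acc / sum(pi_acc)
    if (K > 1) {
      rs <- rowSums(xi_acc)
      nz <- rs > 0
      A[nz, ] <- xi_acc[nz, , drop = FALSE] / rs[nz]
      A[!nz, ] <- 1 / K
    }
    E <- clamp01(em_num / em_den)
  }
  list(pi = pi, A = A, E = E, train_log = train_log,
       loglik = train_log[length(train_log)])
}

#' @export
print.bhmm <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Bernoulli-emission HMM: %d states, %d marks, fitted on %d bins\n",
    x$n_states, length(x$mark_names), x$n_bins))
  cat(sprintf("log-likelihood: %.2f (%d EM iterations)\n",
              x$loglik, length(x$train_log)))
  cat("\nEmission probabilities:\n")
  em <- round(x$emissions, digits)
  dimnames(em) <- list(x$state_names, x$mark_names)
  print(em)
  invisible(x)
}

#' @method summary bhmm
#' @export
summary.bhmm <- function(object, ...) {
  dwell <- 1 / (1 - diag(object$transitions))
  structure(list(model = object, expected_dwell_bins = dwell),
            class = "summary.bhmm")
}

#' @export
print.summary.bhmm <- function(x, ...) {
  print(x$model)
  cat("\nTransition matrix:\n")
  tr <- round(x$model$transitions, 3)
  dimnames(tr) <- list(x$model$state_names, x$model$state_names)
  print(tr)
  cat("\nExpected dwell time (bins):\n")
  print(round(setNames(x$expected_dwell_bins, x$model$state_names), 1))
  invisible(x)
}

#' @method coef bhmm
#' @export
coef.bhmm <- function(object, ...) {
  em <- object$emissions
  dimnames(em) <- list(object$state_names, object$mark_names)
  tr <- object$transitions
  dimnames(tr) <- list(object$state_names, object$state_names)
  list(initial = setNames(object$initial, object$state_names),
       transitions = tr, emissions = em)
}

#' @method logLik bhmm
#' @export
logLik.bhmm <- function(object, ...) {
  K <- object$n_states; M <- length(object$mark_names)
  structure(object$loglik,
            df = (K - 1) + K * (K - 1) + K * M,
            nobs = object$n_bins, class = "logLik")
}

#' Emission heatmap of a fitted chromatin-state model
#'
#' @param x a `bhmm`.
#' @param ... passed to [graphics::image()].
#' @method plot bhmm
#' @export
plot.bhmm <- function(x, ...) {
  E <- x$emissions
  graphics::image(seq_len(ncol(E)), seq_len(nrow(E)), t(E[rev(seq_len(nrow(E))), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  axes = FALSE, xlab = "mark", ylab = "state",
                  zlim = c(0, 1), ...)
  graphics::axis(1, at = seq_len(ncol(E)), labels = x$mark_names, las = 2)
  graphics::axis(2, at = seq_len(nrow(E)), labels = rev(x$state_names), las = 1)
  graphics::box()
  invisible(x)
}

#' Viterbi segmentation under a fitted model
#'
#' Decodes the most probable state path per chromosome; ties are broken
#' toward the lower state index.
#'
#' @param object,model a `bhmm`.
#' @param newdata,data a `binarized_matrix` with the model's marks.
#' @param ... unused.
#' @return a [segmentation()].
#' @export
predict.bhmm <- function(object, newdata, ...) {
  viterbi_segment(object, newdata)
}

#' @rdname predict.bhmm
#' @export
viterbi_segment <- function(model, data) {
  stopifnot(inherits(model, "bhmm"), inherits(data, "binarized_matrix"))
  if (!identical(model$mark_names, data$mark_names))
    stop("mark names of model and data differ")
  logB <- bernoulli_logB(data$values, model$emissions)
  logA <- log(model$transitions); logpi <- log(model$initial)
  labels <- integer(nrow(data$values))
  logprob <- 0
  for (rows in chrom_row_ranges(data$grid)) {
    vt <- .viterbi_path(logpi, logA, logB[rows, , drop = FALSE])
    labels[rows] <- vt$path
    logprob <- logprob + vt$logprob
  }
  seg <- segmentation(data$grid, model$state_names[labels],
                      model$state_names, cell_type = data$cell_type)
  attr(seg, "logprob") <- logprob
  seg
}

#' Simulate tracks from a fitted or hand-built model
#'
#' Draws a hidden state path (restarting from the initial distribution at
#' each chromosome) and Bernoulli mark emissions on a bin grid.
#'
#' @param object a `bhmm`.
#' @param nsim number of replicate simulations.
#' @param seed integer seed.
#' @param grid a `bin_grid` giving the sequence structure.
#' @param ... unused.
#' @return for `nsim = 1` a list with `path` (integer states) and `data`
#'   (a `binarized_matrix`); otherwise a list of such lists.
#' @export
simulate.bhmm <- function(object, nsim = 1, seed = 1L, grid, ...) {
  one <- function(s) {
    with_seed(s, {
      path <- integer(grid$total_bins)
      for (rows in chrom_row_ranges(grid)) {
        path[rows[1]] <- sample.int(object$n_states, 1, prob = object$initial)
        for (t in rows[-1])
          path[t] <- sample.int(object$n_states, 1,
                                prob = object$transitions[path[t - 1L], ])
      }
      V <- matrix(rbinom(grid$total_bins * length(object$mark_names), 1,
                         object$emissions[path, ]),
                  nrow = grid$total_bins)
      colnames(V) <- object$mark_names
      list(path = path,
           data = binarized_matrix(grid, V, object$mark_names, "simulated"))
    })
  }
  if (nsim == 1) return(one(substream(seed, 11L)))
  lapply(seq_len(nsim), function(i) one(substream(seed, 11L + i)))
}

#' Re-estimate emission probabilities from a segmentation
#'
#' Entry (s, m) is the fraction of bins labeled s in which mark m is
#' present. States with zero assigned bins get an NA row, flagged via the
#' `"empty_states"` attribute.
#'
#' @param seg a [segmentation()].
#' @param data a `binarized_matrix` on the same grid.
#' @return states x marks matrix of frequencies.
#' @export
recompute_emissions <- function(seg, data) {
  stopifnot(inherits(seg, "segmentation"), inherits(data, "binarized_matrix"))
  if (!identical(seg$grid, data$grid))
    stop("segmentation and data must share the grid")
  states <- seg$state_names
  E <- matrix(NA_real_, length(states), ncol(data$values),
              dimnames = list(states, data$mark_names))
  f <- factor(seg$labels, levels = states)
  n <- tabulate(f, nbins = length(states))
  sums <- rowsum(data$values, f)
  present <- rownames(sums)
  E[present, ] <- sums / n[match(present, states)]
  attr(E, "empty_states") <- states[n == 0]
  E
}
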