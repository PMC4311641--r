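# Analytic inversion of the encoding model under the mixture prior.
#
# With likelihood y ~ N(B'x, Sigma) and prior x | c ~ N(m_c, R_c), the
# cluster-conditional posterior of x is Gaussian with mean
#   n_c(y) = Q_c fbar(y) + U_c m_c,
# where U_c = (I + R_c D)^{-1}, D = B Sigma^{-1} B', Q_c = U_c R_c and
# fbar(y) = B Sigma^{-1} y.  Cluster responsibilities follow
#   log P(c|y) = log pi_c + 1/2 log det U_c + 1/2 fbar' Q_c fbar
#                - 1/2 m_c' D U_c m_c + fbar' U_c m_c + const,
# normalized by log-sum-exp.  Note R_c is never inverted, so singular
# (moment-estimated) prior covariances are admissible.

#' Precompute the cluster-independent and per-cluster decoder matrices
#'
#' Restricts the encoding model to its selected voxels, forms
#' `D = B Sigma^-1 B'`, and for every mixture component factorizes
#' `I + R_c D` once to obtain `U_c`, `Q_c = U_c R_c` (symmetrized), the
#' log-determinant of `U_c`, and the cached products `U_c m_c` and
#' `m_c' D U_c m_c`.
#'
#' @param model An `encoding_model` (see [fit_encoding_model()]).
#' @param prior A `mixture_prior` over the same pixel space.
#' @param temperature Positive number, or `"hard"` (default) for the
#'   most-probable-cluster limit.
#'
#' @return An object of class `decoder_state`.
#' @export
precompute_state <- function(model, prior, temperature = "hard") {
  stopifnot(inherits(model, "encoding_model"), inherits(prior, "mixture_prior"))
  p <- nrow(model$B)
  if (ncol(prior$means) != p)
    stop("prior pixel dimension ", ncol(prior$means),
         " != encoding model pixel dimension ", p)
  check_temperature(temperature)
  sel <- model$selected
  B <- model$B[, sel, drop = FALSE]
  s2 <- model$sigma2[sel]
  Bw <- sweep(B, 2, s2, "/")           # B Sigma^{-1}
  D <- symmetrize(Bw %*% t(B))
  C <- n_components(prior)
  Ip <- diag(p)
  U <- Q <- vector("list", C)
  logdet_U <- mDUm <- numeric(C)
  Um <- matrix(NA_real_, p, C)
  for (ci in seq_len(C)) {
    R <- prior$covariances[[ci]]
    M <- Ip + R %*% D
    qrM <- qr(M)
    if (qrM$rank < p)
      stop("I + R_c D is singular for cluster ", ci)
    U[[ci]] <- solve(qrM, Ip)
    ld <- determinant(M, logarithm = TRUE)
    logdet_U[ci] <- -as.numeric(ld$modulus)
    Q[[ci]] <- symmetrize(U[[ci]] %*% R)
    m <- prior$means[ci, ]
    Um[, ci] <- U[[ci]] %*% m
    mDUm[ci] <- drop(crossprod(m, D %*% Um[, ci]))
  }
  structure(list(D = D, U = U, Q = Q, logdet_U = logdet_U, Um = Um,
                 mDUm = mDUm, temperature = temperature,
                 selected = sel, p = p, n_components = C),
            class = "decoder_state")
}

check_temperature <- function(temperature) {
  if (identical(temperature, "hard")) return(invisible(TRUE))
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop("temperature must be a positive number or \"hard\"")
  invisible(TRUE)
}

#' @export
print.decoder_state <- function(x, ...) {
  cat("<decoder_state> p = ", x$p, ", ", x$n_components,
      " components, temperature = ",
      if (identical(x$temperature, "hard")) "hard (T -> 0)" else x$temperature,
      "\n", sep = "")
  invisible(x)
}

#' Project a response vector into image space
#'
#' Computes `fbar(y) = B Sigma^-1 y` on the selected-voxel subspace. `y` must
#' already be restricted to the selected voxels and standardized with the
#' model's stored training transform (see [standardize_responses()]).
#'
#' @param model An `encoding_model`.
#' @param y Numeric vector over the selected voxels.
#'
#' @return Numeric vector of length `p`.
#' @export
transform_response <- function(model, y) {
  sel <- model$selected
  if (length(y) != sum(sel))
    stop("y has length ", length(y), "; model selects ", sum(sel), " voxels")
  B <- model$B[, sel, drop = FALSE]
  drop(B %*% (y / model$sigma2[sel]))
}

#' Cluster-conditional posterior mean of the image
#'
#' `n_c(y) = Q_c fbar(y) + U_c m_c`. With a zero prior covariance or an
#' uninformative likelihood (`D = 0`) this collapses to the prior mean.
#'
#' @param state A `decoder_state`.
#' @param f_bar Response projected into image space ([transform_response()]).
#' @param c Cluster index in `1..C`.
#'
#' @return Numeric vector of length `p`.
#' @export
posterior_mean <- function(state, f_bar, c) {
  if (c < 1L || c > state$n_components) stop("cluster index out of range")
  drop(state$Q[[c]] %*% f_bar) + state$Um[, c]
}

#' Log cluster responsibilities given a response
#'
#' Evaluates, per cluster, `log w_c + 1/2 log det U_c + 1/2 fbar' Q_c fbar -
#' 1/2 m_c' D U_c m_c + fbar' U_c m_c` and normalizes with log-sum-exp so the
#' result exponentiates to a simplex (additive constants cancel).
#'
#' @param state A `decoder_state`.
#' @param f_bar Projected response ([transform_response()]).
#' @param log_prior_weights Length-`C` vector of log prior weights; defaults
#'   to the mixture's `log pi_c` when a `prior` is given. Semantic gating
#'   substitutes per-trial `log P(c|z)` here.
#' @param prior Optional `mixture_prior` used only for its weights.
#'
#' @return Length-`C` vector of log responsibilities (floored at -745).
#' @export
log_responsibilities <- function(state, f_bar, log_prior_weights = NULL,
                                 prior = NULL) {
  C <- state$n_components
  if (is.null(log_prior_weights)) {
    if (is.null(prior)) stop("supply log_prior_weights or a prior")
    log_prior_weights <- log(prior$weights)
  }
  if (length(log_prior_weights) != C)
    stop("log_prior_weights must have length ", C)
  if (all(!is.finite(log_prior_weights)))
    stop("all prior weights are zero")
  lp <- numeric(C)
  for (ci in seq_len(C)) {
    lp[ci] <- log_prior_weights[ci] + 0.5 * state$logdet_U[ci] +
      0.5 * drop(crossprod(f_bar, state$Q[[ci]] %*% f_bar)) -
      0.5 * state$mDUm[ci] + drop(crossprod(f_bar, state$Um[, ci]))
  }
  lp <- lp - logsumexp(lp)
  pmax(lp, -745)
}

#' Temperature-weighted reconstruction
#'
#' Mixes the per-cluster posterior means with weights proportional to
#' `P(c|y)^(1/T)`. In the default hard mode (`T` tending to zero) the
#' reconstruction is the posterior mean of the single most probable cluster,
#' ties broken toward the lowest cluster index.
#'
#' @param state A `decoder_state`.
#' @param f_bar Projected response.
#' @param responsibilities Simplex vector of cluster responsibilities.
#' @param temperature Positive number or `"hard"`; defaults to the state's.
#'
#' @return List with `reconstruction` (length-`p` vector) and `winner`
#'   (index of the most responsible cluster).
#' @export
reconstruct <- function(state, f_bar, responsibilities,
                        temperature = state$temperature) {
  check_temperature(temperature)
  C <- state$n_components
  if (length(responsibilities) != C)
    stop("responsibilities must have length ", C)
  winner <- which.max(responsibilities)   # which.max takes the lowest on ties
  if (identical(temperature, "hard")) {
    x <- posterior_mean(state, f_bar, winner)
  } else {
    lw <- log(pmax(responsibilities, 1e-323)) / temperature
    w <- exp(lw - logsumexp(lw))
    x <- numeric(state$p)
    for (ci in seq_len(C)) {
      if (w[ci] > 0) x <- x + w[ci] * posterior_mean(state, f_bar, ci)
    }
  }
  list(reconstruction = x, winner = winner)
}

#' Letter-category probabilities from cluster responsibilities
#'
#' `P(l|y) = sum_c P(c|y) P(l|c)` with `P(l|c)` the prior's per-cluster label
#' frequency table.
#'
#' @param responsibilities Simplex vector over clusters (or `N x C` matrix).
#' @param label_table `C x L` row-stochastic matrix.
#'
#' @return Length-`L` simplex vector (or `N x L` matrix).
#' @export
letter_probability <- function(responsibilities, label_table) {
  if (is.matrix(responsibilities)) return(responsibilities %*% label_table)
  drop(matrix(responsibilities, 1) %*% label_table)
}

#' Decode a batch of response trials
#'
#' Standardizes the responses with the encoding model's stored transform,
#' restricts to selected voxels, and for each trial computes the projected
#' response, cluster responsibilities, reconstruction and (when the prior has
#' a label table) letter-category probabilities. Per-cluster matrices are
#' computed once.
#'
#' @param model An `encoding_model`.
#' @param prior A `mixture_prior`.
#' @param responses A [response_set()] over the model's voxels (raw scale).
#' @param gating_log_weights Optional `N x C` matrix of per-trial log prior
#'   weights (semantic gating, see [gated_log_weights()]); defaults to the
#'   mixture weights for every trial.
#' @param temperature Positive number or `"hard"` (default).
#'
#' @return List of class `decoding_result`: `reconstructions` (`N x p`),
#'   `winners` (length `N`), `responsibilities` (`N x C`), `letter_probs`
#'   (`N x L` or `NULL`) and the `state`.
#' @export
decode_batch <- function(model, prior, responses, gating_log_weights = NULL,
                         temperature = "hard") {
  stopifnot(inherits(responses, "response_set"))
  state <- precompute_state(model, prior, temperature)
  Ys <- standardize_responses(model, responses)[, model$selected, drop = FALSE]
  N <- nrow(Ys)
  C <- state$n_components
  if (!is.null(gating_log_weights)) {
    gating_log_weights <- as.matrix(gating_log_weights)
    if (nrow(gating_log_weights) != N || ncol(gating_log_weights) != C)
      stop("gating_log_weights must be ", N, " x ", C)
  }
  log_pi <- log(prior$weights)
  recon <- matrix(NA_real_, N, state$p)
  resp <- matrix(NA_real_, N, C)
  winners <- integer(N)
  Bw <- model$B[, model$selected, drop = FALSE]
  Fbar <- sweep(Ys, 2, model$sigma2[model$selected], "/") %*% t(Bw)  # N x p
  for (j in seq_len(N)) {
    f <- Fbar[j, ]
    lw <- if (is.null(gating_log_weights)) log_pi else gating_log_weights[j, ]
    lr <- log_responsibilities(state, f, log_prior_weights = lw)
    resp[j, ] <- exp(lr)
    out <- reconstruct(state, f, resp[j, ], temperature)
    recon[j, ] <- out$reconstruction
    winners[j] <- out$winner
  }
  colnames(resp) <- prior$component_names
  letter_probs <- if (!is.null(prior$label_table))
    letter_probability(resp, prior$label_table) else NULL
  structure(list(reconstructions = recon, winners = winners,
                 responsibilities = resp, letter_probs = letter_probs,
                 state = state,
                 winner_names = prior$component_names[winners]),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result> ", nrow(x$reconstructions), " trials, ",
      ncol(x$responsibilities), " components\n", sep = "")
  invisible(x)
}
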