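# First-order linear-chain conditional random field over the BIO label set
# {MC_B, MC_I, O}.  Parameters are state weights (feature string x label)
# and transition weights (label x label); training maximizes the
# L2-regularized conditional log-likelihood with exact forward-backward
# gradients and L-BFGS.  Decoding is Viterbi; a brute-force path enumerator
# is provided as an independent test oracle.

crf_label_order <- c("MC_B", "MC_I", "O") # fixed tie-break order

#' Training configuration for the linear-chain CRF
#'
#' @param l2_penalty Non-negative coefficient of the L2 penalty
#'   `(l2/2)*||w||^2` on the negative conditional log-likelihood.
#' @param max_iterations Maximum L-BFGS iterations.
#' @param seed Integer seed (training itself is deterministic — weights
#'   start at zero — but the seed is recorded and used by any stochastic
#'   consumer).
#' @return Object of class `crf_config`.
#' @export
crf_config <- function(l2_penalty = 1.0, max_iterations = 100L, seed = 1L) {
  if (l2_penalty < 0) stop("l2_penalty must be non-negative")
  if (max_iterations < 1) stop("max_iterations must be positive")
  structure(list(l2_penalty = l2_penalty,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed),
                 label_set = crf_label_order),
            class = "crf_config")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Internal: index sequences against a feature dictionary.
# Returns list of per-sequence lists: fidx (concatenated feature indices,
# 0 for unknown features dropped), tok (token id per feature), n (length).
index_sequences <- function(x, feat_index) {
  lapply(x, function(seq) {
    n <- length(seq)
    fidx_all <- integer(0); tok_all <- integer(0)
    for (t in seq_len(n)) {
      id <- feat_index[seq[[t]]]
      id <- id[!is.na(id)]
      fidx_all <- c(fidx_all, id)
      tok_all <- c(tok_all, rep.int(t, length(id)))
    }
    list(fidx = fidx_all, tok = tok_all, n = n)
  })
}

# State score matrix (n x 3) for one indexed sequence.
state_scores <- function(idx, W) {
  S <- matrix(0, nrow = idx$n, ncol = 3L)
  if (length(idx$fidx) > 0) {
    contrib <- rowsum(W[idx$fidx, , drop = FALSE], group = idx$tok)
    S[as.integer(rownames(contrib)), ] <- contrib
  }
  S
}

# Negative penalized log-likelihood and gradient over all sequences.
crf_obj <- function(par, idx_list, y_list, nfeat, l2, grad = FALSE) {
  W <- matrix(par[seq_len(3L * nfeat)], nrow = nfeat, ncol = 3L)
  Tr <- matrix(par[3L * nfeat + seq_len(9L)], nrow = 3L, ncol = 3L)
  nll <- 0
  if (grad) {
    Wg <- matrix(0, nrow = nfeat, ncol = 3L)
    Tg <- matrix(0, nrow = 3L, ncol = 3L)
  }
  for (s in seq_along(idx_list)) {
    idx <- idx_list[[s]]
    n <- idx$n
    if (n == 0) next
    y <- y_list[[s]]
    S <- state_scores(idx, W)
    # forward
    alpha <- matrix(0, n, 3L)
    alpha[1, ] <- S[1, ]
    if (n > 1) for (t in 2:n) {
      for (j in 1:3) {
        alpha[t, j] <- S[t, j] + logsumexp(alpha[t - 1, ] + Tr[, j])
      }
    }
    logZ <- logsumexp(alpha[n, ])
    gold <- sum(S[cbind(seq_len(n), y)])
    if (n > 1) gold <- gold + sum(Tr[cbind(y[-n], y[-1])])
    nll <- nll + (logZ - gold)
    if (grad) {
      # backward
      beta <- matrix(0, n, 3L)
      if (n > 1) for (t in (n - 1):1) {
        for (i in 1:3) {
          beta[t, i] <- logsumexp(Tr[i, ] + S[t + 1, ] + beta[t + 1, ])
        }
      }
      marg <- exp(alpha + beta - logZ)             # n x 3 state marginals
      obs <- matrix(0, n, 3L); obs[cbind(seq_len(n), y)] <- 1
      diff <- marg - obs
      if (length(idx$fidx) > 0) {
        Wg[idx$fidx, ] <- Wg[idx$fidx, , drop = FALSE] +
          diff[idx$tok, , drop = FALSE]
      }
      if (n > 1) for (t in 2:n) {
        pair <- exp(alpha[t - 1, ] + Tr +
                      matrix(S[t, ] + beta[t, ], 3, 3, byrow = TRUE) - logZ)
        Tg <- Tg + pair
        Tg[y[t - 1], y[t]] <- Tg[y[t - 1], y[t]] - 1
      }
    }
  }
  nll <- nll + (l2 / 2) * sum(par^2)
  if (!grad) return(nll)
  Wg <- Wg + l2 * W
  Tg <- Tg + l2 * Tr
  list(value = nll, gradient = c(as.vector(Wg), as.vector(Tg)))
}

#' Train a linear-chain CRF tagger
#'
#' Fits state and transition weights by maximizing the L2-regularized
#' conditional log-likelihood of the training sequences under a first-order
#' (adjacent-label) chain with global normalization, using exact
#' forward-backward gradients and L-BFGS.  Weights are initialized at zero,
#' so training is deterministic.
#'
#' @param x List of sequences; each sequence is a list of character vectors
#'   of `name=value` feature strings (one vector per token), as produced by
#'   [sentence_features()].
#' @param y List of label vectors over `MC_B`/`MC_I`/`O`, aligned to `x`.
#' @param config A [crf_config()].
#' @return Object of class `mc_crf` with elements `features` (feature
#'   dictionary), `state` (feature-by-label weight matrix), `transitions`
#'   (label-by-label weight matrix), `config`, `loglik` (unpenalized
#'   training conditional log-likelihood), `convergence` and `version`.
#' @seealso [predict.mc_crf()], [crf_save()], [crf_load()]
#' @export
crf_train <- function(x, y, config = crf_config()) {
  if (length(x) == 0) stop("configuration error: empty training set")
  if (length(x) != length(y)) stop("data error: x and y lengths differ")
  for (s in seq_along(x)) {
    if (length(x[[s]]) != length(y[[s]])) {
      stop("data error: sequence ", s, " has ", length(x[[s]]),
           " feature vectors but ", length(y[[s]]), " labels")
    }
    if (!all(y[[s]] %in% crf_label_order)) {
      stop("data error: sequence ", s, " has labels outside {MC_B, MC_I, O}")
    }
  }
  feats <- unique(unlist(x, use.names = FALSE))
  feat_index <- setNames(seq_along(feats), feats)
  idx_list <- index_sequences(x, feat_index)
  y_list <- lapply(y, function(l) match(l, crf_label_order))
  nfeat <- length(feats)
  par0 <- numeric(3L * nfeat + 9L)

  fn <- function(p) crf_obj(p, idx_list, y_list, nfeat, config$l2_penalty)
  gr <- function(p) crf_obj(p, idx_list, y_list, nfeat, config$l2_penalty,
                            grad = TRUE)$gradient
  fit <- optim(par0, fn = fn, gr = gr, method = "L-BFGS-B",
               control = list(maxit = config$max_iterations, factr = 1e7))
  W <- matrix(fit$par[seq_len(3L * nfeat)], nrow = nfeat, ncol = 3L,
              dimnames = list(feats, crf_label_order))
  Tr <- matrix(fit$par[3L * nfeat + seq_len(9L)], nrow = 3L, ncol = 3L,
               dimnames = list(crf_label_order, crf_label_order))
  # unpenalized training log-likelihood for reporting
  ll <- -(crf_obj(fit$par, idx_list, y_list, nfeat, 0))
  structure(list(features = feats, state = W, transitions = Tr,
                 config = config, loglik = ll,
                 convergence = fit$convergence, version = "mc_crf/1"),
            class = "mc_crf")
}

#' @export
print.mc_crf <- function(x, ...) {
  cat("<mc_crf> linear-chain CRF, labels:",
      paste(colnames(x$state), collapse = " "), "\n")
  cat(sprintf("%d features, l2 = %g, training loglik = %.3f\n",
              length(x$features), x$config$l2_penalty, x$loglik))
  invisible(x)
}

#' @export
coef.mc_crf <- function(object, ...) {
  list(state = object$state, transitions = object$transitions)
}

# Per-token state scores for a raw (non-indexed) feature sequence.
seq_state_scores <- function(model, sequence) {
  n <- length(sequence)
  S <- matrix(0, n, 3L)
  fi <- setNames(seq_along(model$features), model$features)
  for (t in seq_len(n)) {
    id <- fi[sequence[[t]]]
    id <- id[!is.na(id)]
    if (length(id)) S[t, ] <- colSums(model$state[id, , drop = FALSE])
  }
  S
}

#' Viterbi decoding of a feature sequence
#'
#' Returns the maximum-a-posteriori BIO label path.  Ties are broken toward
#' the fixed label order `MC_B < MC_I < O`.
#'
#' @param object A fitted `mc_crf`.
#' @param sequence List of per-token feature vectors (one sentence); an
#'   empty sequence yields an empty label vector.
#' @param ... Unused.
#' @return Character vector of labels.
#' @export
predict.mc_crf <- function(object, sequence, ...) {
  n <- length(sequence)
  if (n == 0) return(character(0))
  S <- seq_state_scores(object, sequence)
  Tr <- object$transitions
  delta <- matrix(-Inf, n, 3L)
  back <- matrix(0L, n, 3L)
  delta[1, ] <- S[1, ]
  if (n > 1) for (t in 2:n) {
    for (j in 1:3) {
      cand <- delta[t - 1, ] + Tr[, j]
      b <- which.max(cand) # first max = fixed label-order tie-break
      back[t, j] <- b
      delta[t, j] <- cand[b] + S[t, j]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in n:2) path[t - 1L] <- back[t, path[t]]
  crf_label_order[path]
}

#' Brute-force decoding oracle
#'
#' Enumerates all `3^n` label paths in lexicographic order (label order
#' `MC_B < MC_I < O`, leftmost position most significant) and returns the
#' first path attaining the maximum score.  Exists solely as the
#' independent decoding oracle for tests; guarded to short sequences.
#'
#' @param model A fitted `mc_crf`.
#' @param sequence List of per-token feature vectors.
#' @param max_n Guard on sequence length (default 12).
#' @return Character vector of labels.
#' @export
predict_brute_force <- function(model, sequence, max_n = 12L) {
  n <- length(sequence)
  if (n > max_n) stop("guard error: sequence length ", n, " exceeds ", max_n)
  if (n == 0) return(character(0))
  S <- seq_state_scores(model, sequence)
  Tr <- model$transitions
  grid <- as.matrix(expand.grid(rev(replicate(n, 1:3, simplify = FALSE)),
                                KEEP.OUT.ATTRS = FALSE))[, n:1, drop = FALSE]
  scores <- numeric(nrow(grid))
  for (t in seq_len(n)) {
    scores <- scores + S[t, grid[, t]]
    if (t > 1) scores <- scores + Tr[cbind(grid[, t - 1L], grid[, t])]
  }
  # first row attaining the max = lexicographically-first optimal path
  crf_label_order[grid[which.max(scores), ]]
}

#' Save / load a CRF model as a self-describing JSON artifact
#'
#' The artifact carries a format-version field; predictions are identical
#' after a save/load round trip (weights are written at full precision).
#'
#' @param model A fitted `mc_crf`.
#' @param path File path (conventionally `.json`).
#' @export
crf_save <- function(model, path) {
  stopifnot(inherits(model, "mc_crf"))
  obj <- list(
    format = model$version,
    labels = crf_label_order,
    features = model$features,
    state = as.vector(model$state),
    transitions = as.vector(model$transitions),
    config = unclass(model$config),
    loglik = model$loglik,
    convergence = model$convergence
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname crf_save
#' @return `crf_load`: the restored `mc_crf`.
#' @export
crf_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mc_crf/1")) {
    stop("unsupported model format: ", obj$format)
  }
  nfeat <- length(obj$features)
  W <- matrix(obj$state, nrow = nfeat, ncol = 3L,
              dimnames = list(obj$features, crf_label_order))
  Tr <- matrix(obj$transitions, nrow = 3L, ncol = 3L,
               dimnames = list(crf_label_order, crf_label_order))
  cfg <- crf_config(obj$config$l2_penalty, obj$config$max_iterations,
                    obj$config$seed)
  structure(list(features = obj$features, state = W, transitions = Tr,
                 config = cfg, loglik = obj$loglik,
                 convergence = obj$convergence, version = obj$format),
            class = "mc_crf")
}
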