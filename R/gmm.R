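# Adaptive per-pixel Gaussian-mixture background subtraction
# (Stauffer-Grimson style), the comparison baseline for the wavelet
# pipeline. Vectorized over pixels; K mixture components per pixel.

.gmm_new <- function(frame, K, var_init) {
  np <- length(frame)
  list(K = K,
       w  = cbind(rep(1, np), matrix(0, np, K - 1)),
       mu = cbind(as.vector(frame), matrix(0, np, K - 1)),
       v  = matrix(var_init, np, K),
       var_init = var_init)
}

.gmm_update <- function(model, frame, lr = 0.05, match_sigma = 2.5,
                        var_min = 4) {
  x <- as.vector(frame)
  K <- model$K
  d <- abs(x - model$mu)
  sd_ <- sqrt(model$v)
  matched <- d <= match_sigma * sd_ & model$w > 0
  prio <- model$w / sd_
  prio[!matched] <- -Inf
  best <- max.col(prio, ties.method = "first")
  has_match <- matched[cbind(seq_along(x), best)]
  sel <- cbind(seq_along(x), best)
  # matched pixels: standard running update of the winning component
  own <- matrix(0, length(x), K)
  own[sel] <- as.numeric(has_match)
  model$w <- (1 - lr) * model$w + lr * own
  mu_b <- model$mu[sel]; v_b <- model$v[sel]
  diff <- x - mu_b
  mu_b <- mu_b + lr * diff * has_match
  v_b <- v_b + lr * (diff^2 - v_b) * has_match
  model$mu[sel] <- mu_b
  model$v[sel] <- pmax(v_b, var_min)
  # unmatched pixels: replace the weakest component
  if (any(!has_match)) {
    weak <- max.col(-model$w, ties.method = "first")
    i <- which(!has_match)
    si <- cbind(i, weak[i])
    model$w[si] <- lr
    model$mu[si] <- x[i]
    model$v[si] <- model$var_init
  }
  model$w <- model$w / rowSums(model$w)
  model
}

# Per-pixel foreground score: normalized distance of the observation to the
# closest background-designated component (higher = more foreground-like).
.gmm_score <- function(model, frame, background_weight = 0.7) {
  x <- as.vector(frame)
  sd_ <- sqrt(model$v)
  prio <- model$w / sd_
  np <- length(x); K <- model$K
  ord <- matrix(0L, np, K)
  tmp <- prio
  for (kk in seq_len(K)) {
    m <- max.col(tmp, ties.method = "first")
    ord[, kk] <- m
    tmp[cbind(seq_len(np), m)] <- -Inf
  }
  # number of background components: smallest prefix (in priority order)
  # whose cumulative weight reaches background_weight
  cum <- numeric(np)
  nbg <- rep(K, np)
  done <- rep(FALSE, np)
  for (kk in seq_len(K)) {
    cum <- cum + model$w[cbind(seq_len(np), ord[, kk])]
    hit <- !done & cum >= background_weight
    nbg[hit] <- kk
    done <- done | hit
  }
  score <- rep(Inf, np)
  for (kk in seq_len(K)) {
    use <- nbg >= kk
    ci <- ord[, kk]
    dk <- abs(x - model$mu[cbind(seq_len(np), ci)]) /
      sd_[cbind(seq_len(np), ci)]
    score[use] <- pmin(score[use], dk[use])
  }
  matrix(score, nrow(frame), ncol(frame))
}

#' GMM background-subtraction baseline
#'
#' Trains an adaptive per-pixel Gaussian mixture on the first `history`
#' frames, then classifies every remaining frame: a pixel is raw foreground
#' when it lies further than `match_sigma` standard deviations from every
#' background-designated component. Raw masks are post-processed with the
#' same [combine_and_extract()] path as the primary pipeline, using the MMD
#' boundary against `reference` when one is supplied.
#'
#' @param frames list of numeric matrices (the full sequence, warm-up
#'   first).
#' @param history number of initial frames used to build the background
#'   model (must be `>= 1` and `< length(frames)`).
#' @param reference optional reference frame for the boundary mask; `NULL`
#'   post-processes with an empty boundary.
#' @param params a [detect_params()] object for the post-processing.
#' @param n_components mixture size per pixel (default 3).
#' @param learning_rate model adaptation rate (default 0.05).
#' @param background_weight cumulative weight defining the background
#'   components (default 0.7).
#' @param match_sigma match distance in standard deviations (default 2.5).
#' @param levels wavelet depth for the boundary MMD (default 3).
#' @return `list(masks, raw_masks, scores, results)`: post-processed masks,
#'   raw threshold masks, foreground score maps, and the
#'   `detection_result`s, one per frame after the warm-up.
#' @export
run_gmm_baseline <- function(frames, history, reference = NULL,
                             params = detect_params(), n_components = 3L,
                             learning_rate = 0.05, background_weight = 0.7,
                             match_sigma = 2.5, levels = 3L) {
  if (length(frames) <= history)
    stop(sprintf("need more than 'history' = %d frames, got %d",
                 history, length(frames)))
  if (history < 1L) stop("'history' must be >= 1")
  frames <- lapply(frames, .as_gray)
  model <- .gmm_new(frames[[1]], n_components, var_init = 225)
  for (i in seq_len(history)[-1])
    model <- .gmm_update(model, frames[[i]], learning_rate, match_sigma)
  pyr_r <- if (!is.null(reference))
    dwt_decompose(.as_gray(reference), levels) else NULL
  test_idx <- (history + 1L):length(frames)
  masks <- raw_masks <- scores <- results <- vector("list", length(test_idx))
  for (ii in seq_along(test_idx)) {
    f <- frames[[test_idx[ii]]]
    sc <- .gmm_score(model, f, background_weight)
    raw <- sc > match_sigma
    bou <- if (is.null(pyr_r)) matrix(FALSE, nrow(f), ncol(f))
           else boundary_by_mmd(mmd_map(dwt_decompose(f, levels), pyr_r), params)
    res <- combine_and_extract(raw, bou, params)
    masks[[ii]] <- res$mask; raw_masks[[ii]] <- raw
    scores[[ii]] <- sc; results[[ii]] <- res
  }
  list(masks = masks, raw_masks = raw_masks, scores = scores,
       results = results)
}
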