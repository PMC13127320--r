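#' STAPLE consensus of multiple readers' volumes
#'
#' Simultaneous truth and performance level estimation: an
#' expectation-maximization fixed point of the binary model in which each
#' rater segments a hidden true volume with unknown sensitivity `p_j` and
#' specificity `q_j`. The E-step combines the current `p_j`, `q_j` and the
#' foreground prior into per-voxel truth probabilities; the M-step
#' re-estimates `p_j`, `q_j` from those weights. Iteration stops when the
#' largest parameter change falls below `tol` or after `max_iter` steps.
#'
#' @param rater_masks A list of [structure_mask()] objects on one common grid.
#' @param prior Scalar prior probability that a voxel is foreground, or a
#'   voxelwise array; defaults to the mean rater foreground fraction.
#' @param tol Convergence tolerance on `max(|dp|, |dq|)` (default 1e-6).
#' @param max_iter Maximum EM iterations (default 100).
#' @param init Initial sensitivity/specificity for every rater (default 0.99).
#' @param threshold Consensus threshold on the truth probability; voxels at
#'   exactly the threshold are included in the consensus mask.
#' @return A `staple_result`: `consensus_prob` (3D array),
#'   `consensus_mask` ([structure_mask()]), `sensitivity`, `specificity`
#'   (per rater), `loglik_trace`, `iterations`, `converged`.
#' @export
staple <- function(rater_masks, prior = NULL, tol = 1e-6, max_iter = 100,
                   init = 0.99, threshold = 0.5) {
  if (length(rater_masks) < 1L) abort_domain("need at least one rater mask")
  purrr::walk(rater_masks, assert_mask)
  ref <- rater_masks[[1]]
  purrr::walk(rater_masks, assert_same_grid, b = ref)
  d <- purrr::map(rater_masks, ~ as.numeric(.x$voxels))
  D <- do.call(cbind, d) # voxels x raters
  if (all(D == 0)) abort_domain("all rater masks are empty: consensus undefined")
  J <- ncol(D)
  nvox <- nrow(D)
  if (is.null(prior)) prior <- mean(D)
  prior_fg <- if (length(prior) == 1L) rep(prior, nvox) else as.numeric(prior)
  prior_fg <- pmin(pmax(prior_fg, 1e-12), 1 - 1e-12)
  clamp <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  p <- rep(clamp(init), J)
  q <- rep(clamp(init), J)
  loglik <- numeric(0)
  converged <- FALSE
  w <- NULL
  for (it in seq_len(max_iter)) {
    # E-step in log space
    la <- log(prior_fg) + D %*% log(p) + (1 - D) %*% log(1 - p)
    lb <- log(1 - prior_fg) + D %*% log(1 - q) + (1 - D) %*% log(q)
    m <- pmax(la, lb)
    ll <- sum(m + log(exp(la - m) + exp(lb - m)))
    loglik <- c(loglik, ll)
    w <- as.numeric(1 / (1 + exp(lb - la)))
    # M-step
    sw <- sum(w); swc <- sum(1 - w)
    p_new <- clamp(as.numeric(crossprod(D, w)) / sw)
    q_new <- clamp(as.numeric(crossprod(1 - D, 1 - w)) / swc)
    delta <- max(abs(p_new - p), abs(q_new - q))
    p <- p_new; q <- q_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (length(loglik) > 1 && any(diff(loglik) < -1e-8 * pmax(1, abs(loglik[-1])))) {
    rlang::warn("STAPLE log-likelihood decreased between iterations",
                class = "adaptbias_staple_monotonicity")
  }
  prob <- array(w, dim = dim(ref$voxels))
  cons <- structure_mask(prob >= threshold, spacing = ref$spacing,
                         origin = ref$origin, id = "staple_consensus")
  structure(
    list(consensus_prob = prob, consensus_mask = cons,
         sensitivity = p, specificity = q,
         rater_ids = purrr::map_chr(rater_masks, ~ .x$id %||% NA_character_),
         loglik_trace = loglik, iterations = length(loglik),
         converged = converged, prior = prior),
    class = "staple_result"
  )
}

#' @exportS3Method base::print
print.staple_result <- function(x, ...) {
  cat(sprintf(
    "<staple_result> %d raters, %d EM iterations (%s); consensus %d voxels\n",
    length(x$sensitivity), x$iterations,
    if (x$converged) "converged" else "max_iter reached",
    sum(x$consensus_mask$voxels)))
  invisible(x)
}

#' @describeIn staple Per-rater sensitivity/specificity as a tibble.
#' @param x A `staple_result`.
#' @param ... Unused.
#' @export
tidy.staple_result <- function(x, ...) {
  tibble::tibble(
    rater = ifelse(is.na(x$rater_ids), paste0("rater_", seq_along(x$sensitivity)),
                   x$rater_ids),
    sensitivity = x$sensitivity, specificity = x$specificity
  )
}

#' @describeIn staple One-row convergence summary.
#' @export
glance.staple_result <- function(x, ...) {
  tibble::tibble(
    n_raters = length(x$sensitivity), iterations = x$iterations,
    converged = x$converged, loglik = x$loglik_trace[x$iterations],
    consensus_voxels = sum(x$consensus_mask$voxels)
  )
}

#' @describeIn staple Log-likelihood trace plot.
#' @param object A `staple_result`.
#' @export
autoplot.staple_result <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loglik_trace),
                       loglik = object$loglik_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$loglik)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "EM iteration", y = "log-likelihood",
                  title = "STAPLE convergence") +
    ggplot2::theme_minimal()
}
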