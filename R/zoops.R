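#' De novo motif discovery by ZOOPS expectation-maximisation
#'
#' Minimal single-width motif discovery under the "zero or one occurrence
#' per sequence" model: each sequence either contains one motif site at an
#' unknown offset (prior probability gamma, offset uniform) or is pure
#' background. The E-step computes the posterior over (no site, site at each
#' offset) under the current PWM; the M-step re-estimates the PWM from the
#' expected letter counts (with pseudocounts) and gamma from the expected
#' number of sites. `n_starts` restarts are seeded from randomly chosen data
#' windows and the highest-likelihood fit is returned. Deterministic given
#' `seed`; sites are modelled on the given strand only.
#'
#' @param sequences character vector of ACGT sequences, all at least
#'   `width` long.
#' @param width motif width (>= 4).
#' @param n_starts number of fully converged EM restarts (default 5).
#' @param n_candidates number of data-window starting points screened with
#'   two EM iterations before the best `n_starts` are run to convergence
#'   (default 20 per restart). Screening many starts makes it likely that at
#'   least one seed window is a true motif instance.
#' @param seed integer seed.
#' @param background length-4 background probabilities (default: the
#'   empirical base composition of `sequences`).
#' @param pseudocount total pseudocount mass per position in the M-step.
#' @param max_iter,tol EM stopping rule (log-likelihood change below `tol`).
#' @return A `pwm` with attributes `log_likelihood` and `gamma`.
#' @export
discover_motif_zoops_em <- function(sequences, width, n_starts = 5,
                                    n_candidates = 20 * n_starts, seed = 1,
                                    background = NULL, pseudocount = 0.5,
                                    max_iter = 100, tol = 1e-6) {
  if (width < 4) stopf("width must be >= 4")
  codes <- lapply(sequences, encode_dna)
  if (any(vapply(codes, anyNA, logical(1))))
    stopf("sequences must be over ACGT only")
  lens <- lengths(codes)
  if (any(lens < width)) stopf("width exceeds the shortest sequence length")
  if (is.null(background)) {
    tab <- tabulate(unlist(codes), 4)
    background <- (tab + 1) / (sum(tab) + 4)
  }
  log_bg <- log(background)
  bg_ll_total <- sum(log_bg[unlist(codes)])  # constant across iterations

  ## group sequences by length so each group is a dense code matrix
  groups <- lapply(split(seq_along(codes), lens), function(ix) {
    list(C = do.call(rbind, codes[ix]),
         m = lens[ix[1]] - width + 1)
  })

  run_em <- function(init_probs, iter_cap = max_iter) {
    probs <- init_probs
    gamma <- 0.5
    ll_old <- -Inf
    ll <- NA_real_
    for (iter in seq_len(iter_cap)) {
      llr <- log(probs) - rep(log_bg, each = width)  # width x 4, natural log
      exp_counts <- matrix(0, width, 4)
      z_sum <- 0
      n_seq <- 0
      ll <- bg_ll_total
      for (g in groups) {
        C <- g$C
        m <- g$m
        n <- nrow(C)
        S <- matrix(0, n, m)
        for (i in seq_len(width))
          S <- S + matrix(llr[i, C[, i:(i + m - 1), drop = FALSE]], n, m)
        M <- pmax(apply(S, 1, max), 0)
        W <- exp(S - M)                       # n x m, scaled ratios
        num <- (gamma / m) * W
        denom <- (1 - gamma) * exp(-M) + rowSums(num)
        P <- num / denom                      # posterior site-at-offset
        z_sum <- z_sum + sum(P)
        n_seq <- n_seq + n
        ll <- ll + sum(M + log(denom))
        for (i in seq_len(width)) {
          Ci <- C[, i:(i + m - 1), drop = FALSE]
          for (b in 1:4)
            exp_counts[i, b] <- exp_counts[i, b] + sum(P[Ci == b])
        }
      }
      probs <- sweep(exp_counts, 2, pseudocount * background, "+")
      probs <- probs / rowSums(probs)
      gamma <- min(max(z_sum / n_seq, 1e-6), 1 - 1e-6)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(probs = probs, ll = ll, gamma = gamma)
  }

  best <- with_seed(seed, {
    ## seed candidate PWMs from random data windows, screen each with two
    ## EM iterations, then fully converge the most promising
    inits <- lapply(seq_len(n_candidates), function(t) {
      s <- sample.int(length(codes), 1)
      off <- sample.int(lens[s] - width + 1, 1)
      win <- codes[[s]][off:(off + width - 1)]
      init <- matrix((1 - 0.7) / 3, width, 4)
      init[cbind(seq_len(width), win)] <- 0.7
      init
    })
    screened <- lapply(inits, run_em, iter_cap = 2)
    top <- order(vapply(screened, `[[`, numeric(1), "ll"),
                 decreasing = TRUE)[seq_len(min(n_starts, n_candidates))]
    fits <- lapply(top, function(i) run_em(screened[[i]]$probs))
    fit <- fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]
    ## phase refinement: EM converges readily to a shifted register of the
    ## true motif; re-run from column-shifted versions of the best PWM and
    ## keep the highest-likelihood phase
    for (d in c(-2, -1, 1, 2)) {
      shifted <- matrix(rep(background, each = width), width, 4)
      src <- seq_len(width) + d
      ok <- src >= 1 & src <= width
      shifted[ok, ] <- fit$probs[src[ok], ]
      cand <- run_em(shifted)
      if (cand$ll > fit$ll) fit <- cand
    }
    fit
  })
  out <- pwm_from_probs(best$probs, background = background,
                        motif_id = sprintf("zoops_w%d", width))
  attr(out, "log_likelihood") <- best$ll
  attr(out, "gamma") <- best$gamma
  out
}
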