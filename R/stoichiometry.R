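#' Visible photobleaching-step distribution for n subunits
#'
#' Each of the n labeled subunits of a complex carries a matured (active)
#' chromophore independently with probability m; only complexes with at
#' least one active chromophore are seen at all. The number of observed
#' bleaching steps j is therefore binomial conditioned on visibility:
#' `P(j | n, m) = C(n, j) m^j (1 - m)^(n - j) / (1 - (1 - m)^n)` for
#' j = 1..n.
#'
#' @param n true subunit copy number (>= 1).
#' @param m chromophore maturation probability (0 < m <= 1).
#' @return named numeric vector of probabilities over j = 1..n (sums to 1).
#' @examples
#' visibleStepPmf(2, 0.75)   # 0.4, 0.6
#' @export
visibleStepPmf <- function(n, m) {
    stopifnot(n >= 1)
    if (m <= 0) stop("m = 0 leaves nothing visible")
    if (m > 1) stop("m must be <= 1")
    j <- seq_len(n)
    p <- stats::dbinom(j, n, m) / (1 - (1 - m)^n)
    stats::setNames(p, j)
}

# component pmf matrix P[n, j] over j = 1..jMax for n = 1..nMax
stepPmfMatrix <- function(nMax, m, jMax) {
    P <- matrix(0, nrow = nMax, ncol = jMax,
                dimnames = list(seq_len(nMax), seq_len(jMax)))
    for (n in seq_len(nMax)) {
        p <- visibleStepPmf(n, m)
        jj <- seq_len(min(n, jMax))
        P[n, jj] <- p[jj]
        # probability mass beyond jMax (never the case when jMax >= nMax)
        if (n > jMax) P[n, ] <- P[n, ] / sum(P[n, ])
    }
    P
}

speciesName <- function(n) {
    nm <- c("monomer", "dimer", "trimer", "tetramer", "pentamer", "hexamer")
    ifelse(n <= length(nm), nm[n], paste0(n, "-mer"))
}

#' Infer subunit stoichiometry from a photobleaching step distribution
#'
#' Fits maximum-likelihood mixture weights over true copy numbers
#' n = 1..`nMax` to an observed step-count histogram under the
#' [visibleStepPmf()] dark-fraction model, by expectation-maximization with
#' random restarts (weights-only EM on a multinomial mixture; the
#' log-likelihood is concave in the weights, restarts guard the boundary).
#' The dominant-species call lists every n with weight >= `callThreshold`.
#' Run the fit at `m = 1` to read the histogram raw (no dark-fraction
#' correction).
#'
#' @param dist a [StepDistribution-class], or a named numeric vector of
#'   step-count frequencies (names = step counts).
#' @param m chromophore maturation probability (0 < m <= 1; default 0.75, a
#'   conventional YFP-class estimate -- an assumption, not a measurement).
#' @param nMax largest copy number considered (default 4).
#' @param callThreshold minimum weight for a species to enter the call
#'   (default 0.1).
#' @param nRestarts EM restarts from random weights (default 10).
#' @param seed seed for the restart draws (local; the caller's RNG stream is
#'   untouched).
#' @return a [StoichiometryEstimate-class].
#' @examples
#' h <- c("1" = 400, "2" = 600)
#' inferStoichiometry(h, m = 0.75)
#' @export
inferStoichiometry <- function(dist, m = 0.75, nMax = 4L,
                               callThreshold = 0.1, nRestarts = 10L,
                               seed = 1L) {
    h <- if (is(dist, "StepDistribution")) stepCounts(dist) else dist
    h <- h[as.integer(names(h)) >= 1L]
    if (!length(h) || sum(h) <= 0)
        stop("degenerate step histogram: no accepted traces")
    if (m <= 0 || m > 1) stop("m must lie in (0, 1]")
    js <- as.integer(names(h))
    jMax <- max(js, nMax)
    nMax <- max(nMax, max(js))   # never exclude an observed step count
    counts <- numeric(jMax)
    counts[js] <- as.numeric(h)
    P <- stepPmfMatrix(nMax, m, jMax)
    N <- sum(counts)

    emFit <- function(w) {
        prev <- -Inf
        for (it in seq_len(5000L)) {
            mix <- as.numeric(w %*% P)            # P(j) under the mixture
            mix[mix <= 0] <- .Machine$double.xmin
            ll <- sum(counts * log(mix))
            if (ll - prev < 1e-13 * max(1, abs(ll))) break
            prev <- ll
            resp <- (w * P) / rep(mix, each = nMax) # r[n, j]
            w <- as.numeric(resp %*% counts) / N
            w <- pmax(w, 0); w <- w / sum(w)
        }
        list(w = w, ll = ll)
    }

    fits <- withLocalSeed(seed, {
        starts <- c(list(rep(1 / nMax, nMax)),
                    lapply(seq_len(nRestarts - 1L), function(i) {
                        g <- stats::rgamma(nMax, 1); g / sum(g)
                    }))
        lapply(starts, emFit)
    })
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]
    w <- stats::setNames(best$w, seq_len(nMax))
    predicted <- stats::setNames(as.numeric(w %*% P), seq_len(jMax))
    dominant <- which(w >= callThreshold)
    call <- if (length(dominant))
        paste(speciesName(dominant), collapse = " + ") else
        speciesName(which.max(w))
    new("StoichiometryEstimate", weights = w, maturation = m,
        logLik = best$ll, predicted = predicted,
        observed = stats::setNames(counts, seq_len(jMax)), call = call)
}

#' Correct an observed co-complex fraction for dark partners
#'
#' A partner labeled with a chromophore that matures with probability m is
#' invisible with probability 1 - m, so the observed colocalization fraction
#' underestimates the true co-complex fraction: for monomeric partners,
#' `true = observed / m`, capped at 1.
#'
#' @param observed observed co-complex proportion in `[0, 1]`.
#' @param mPartner partner-channel maturation probability (0 < m <= 1).
#' @return list with `corrected`, `capped` (logical), `observed`,
#'   `mPartner`.
#' @examples
#' coComplexFractionCorrection(0.3, 0.6)$corrected  # 0.5
#' @export
coComplexFractionCorrection <- function(observed, mPartner) {
    stopifnot(observed >= 0, observed <= 1)
    if (mPartner <= 0 || mPartner > 1) stop("mPartner must lie in (0, 1]")
    raw <- observed / mPartner
    list(corrected = min(raw, 1), capped = raw > 1, observed = observed,
         mPartner = mPartner)
}
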