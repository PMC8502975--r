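# new("HeapsFit", C = ...) would partial-match new()'s Class argument (and
# a parameter named Class here would be matched by C = too), so fit objects
# are built by slot assignment behind a partial-match-proof parameter name.
.make_fit <- function(.class_name, ...) {
    obj <- methods::new(.class_name)
    args <- list(...)
    for (nm in names(args)) methods::slot(obj, nm) <- args[[nm]]
    validObject(obj)
    obj
}

#' Construct a Heaps-law fit object from known coefficients
#'
#' Mostly useful to evaluate [newGenesAtNext()] for published coefficients
#' without refitting.
#'
#' @param A,B,C coefficients of y = A * x^B + C.
#' @param rss residual sum of squares (0 when unknown).
#' @return a [HeapsFit-class] with openness classified from B.
#' @examples
#' newGenesAtNext(heapsFit(624.45, 0.48, 3033.86), 17)
#' @export
heapsFit <- function(A, B, C, rss = 0) {
    .make_fit("HeapsFit", A = A, B = B, C = C, rss = rss,
              openness = classifyOpenness(B), converged = TRUE)
}

#' Partition families into core, dispensable and strain-specific
#'
#' Core families are present (any copy count) in every strain, dispensable
#' families in at least two but not all strains, strain-specific families in
#' exactly one. The partition identity
#' \code{nPan == nCore + nDispensable + nSpecific} holds on every input.
#'
#' @param mat a [PresenceAbsenceMatrix-class] with at least two strains
#'   (with one strain every family would be simultaneously core and
#'   specific, so single-strain matrices are rejected).
#' @return a [PanPartition-class].
#' @examples
#' m <- new("PresenceAbsenceMatrix",
#'          counts = matrix(c(1L,1L,0L, 1L,1L,0L, 1L,0L,1L), nrow = 3,
#'                          dimnames = list(c("f1","f2","f3"),
#'                                          c("s1","s2","s3"))))
#' panPartition(m)
#' @export
panPartition <- function(mat) {
    m <- famCounts(mat)
    n <- ncol(m)
    if (n < 2L)
        .stop_input("partition needs at least 2 strains, got %d", n)
    pres <- m > 0L
    occ <- rowSums(pres)
    spec_rows <- occ == 1L
    per_strain <- colSums(pres[spec_rows, , drop = FALSE])
    new("PanPartition",
        nPan = nrow(m),
        nCore = sum(occ == n),
        nDispensable = sum(occ > 1L & occ < n),
        nSpecific = sum(spec_rows),
        perStrainSpecific = setNames(as.integer(per_strain), colnames(m)))
}

#' Permutation-sampled pan, core and new-gene curves
#'
#' For each sampled random ordering of the strains and each prefix length
#' x, records the cumulative number of distinct families (pan curve), the
#' number of families present in all of the first x strains (core curve)
#' and the number of families first seen at step x (new-gene curve), then
#' takes the median over orderings at each x. When the number of requested
#' orderings is at least the number of permutations, all permutations are
#' enumerated exhaustively; otherwise a seeded random sample is drawn.
#'
#' @param mat a [PresenceAbsenceMatrix-class].
#' @param nOrderings maximum number of orderings to sample (default 1000).
#' @param seed integer seed for the permutation sample.
#' @return a [PanCurves-class].
#' @seealso [fitHeaps()], [fitCoreExponential()]
#' @export
sampleCurves <- function(mat, nOrderings = 1000L, seed = 1L) {
    if (nOrderings < 1L) .stop_input("nOrderings must be >= 1")
    pres <- famCounts(mat) > 0L
    n <- ncol(pres)
    exhaustive <- factorial(n) <= nOrderings
    perms <- if (exhaustive) {
        .all_perms(n)
    } else {
        .with_seed(seed, replicate(nOrderings, sample.int(n),
                                   simplify = FALSE))
    }
    k <- length(perms)
    pan_s <- core_s <- new_s <- matrix(0L, k, n)
    for (o in seq_len(k)) {
        perm <- perms[[o]]
        seen <- logical(nrow(pres))
        inall <- rep(TRUE, nrow(pres))
        prev <- 0L
        for (x in seq_len(n)) {
            col <- pres[, perm[x]]
            seen <- seen | col
            inall <- inall & col
            pan_s[o, x] <- sum(seen)
            core_s[o, x] <- sum(inall)
            new_s[o, x] <- pan_s[o, x] - prev
            prev <- pan_s[o, x]
        }
    }
    med <- function(m) data.frame(x = seq_len(n),
                                  y_median = apply(m, 2L, median))
    new("PanCurves", pan = med(pan_s), core = med(core_s), new = med(new_s),
        samples = list(pan = pan_s, core = core_s, new = new_s),
        nOrderings = k, exhaustive = exhaustive)
}

.curve_xy <- function(obj, which) {
    if (is(obj, "PanCurves")) {
        df <- slot(obj, which)
        list(x = df$x, y = df$y_median)
    } else if (is.data.frame(obj)) {
        list(x = obj$x, y = obj$y_median)
    } else {
        .stop_input("expected a PanCurves or a data.frame(x, y_median)")
    }
}

.multi_start_fit <- function(x, y, formula, starts) {
    fits <- list()
    for (st in starts) {
        fit <- tryCatch(
            minpack.lm::nlsLM(formula, data = data.frame(x = x, y = y),
                              start = st,
                              control = minpack.lm::nls.lm.control(
                                  maxiter = 500)),
            error = function(e) NULL, warning = function(w) NULL)
        if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
    }
    if (!length(fits))
        .stop_fit("nonlinear fit failed to converge from any of %d starts (n = %d points, y range [%g, %g])",
                  length(starts), length(x), min(y), max(y))
    rss <- vapply(fits, function(f) sum(residuals(f)^2), 0)
    best <- fits[[which.min(rss)]]
    list(coef = coef(best), rss = min(rss))
}

#' Fit the Heaps-law model to the pan-genome curve
#'
#' Nonlinear least squares of \code{y = A * x^B + C} on the pan-curve
#' medians, with multi-start initialization (positive-A starts with B in
#' 0.1/0.5/0.9 for growing curves, negative-A/negative-B starts for
#' saturating curves) and the lowest-residual converged fit retained. The
#' exponent B plays the role of the openness parameter gamma: the
#' pan-genome is classified open exactly when 0 < B < 1 strictly. A fitted
#' B within 1e-6 of the boundaries 0 or 1 is snapped onto the boundary so
#' that data generated from an exactly linear or constant law classify as
#' closed. A constant curve short-circuits to the degenerate fit A = 0,
#' C = y.
#'
#' @param curve a [PanCurves-class] (its pan component is used) or a
#'   data.frame with columns \code{x} and \code{y_median}; at least 4
#'   points with strictly increasing x.
#' @return a [HeapsFit-class].
#' @examples
#' x <- 1:17
#' fitHeaps(data.frame(x = x, y_median = 624.45 * x^0.48 + 3033.86))
#' @export
fitHeaps <- function(curve) {
    xy <- .curve_xy(curve, "pan")
    x <- xy$x; y <- xy$y
    if (length(x) < 4L) .stop_input("need at least 4 curve points")
    if (any(diff(x) <= 0)) .stop_input("x must be strictly increasing")
    if (diff(range(y)) < .Machine$double.eps * max(1, abs(y[1]))) {
        return(.make_fit("HeapsFit", A = 0, B = 0, C = y[1], rss = 0,
                         openness = "closed", converged = FALSE))
    }
    d <- max(y) - min(y)
    starts <- c(lapply(c(0.1, 0.5, 0.9),
                       function(b) list(A = d, B = b, C = min(y))),
                list(list(A = -d, B = -0.5, C = max(y)),
                     list(A = -d, B = -1, C = max(y))))
    fit <- .multi_start_fit(x, y, y ~ A * x^B + C, starts)
    B <- unname(fit$coef["B"])
    if (abs(B) < 1e-6) B <- 0
    if (abs(B - 1) < 1e-6) B <- 1
    .make_fit("HeapsFit", A = unname(fit$coef["A"]), B = B,
              C = unname(fit$coef["C"]), rss = fit$rss,
              openness = classifyOpenness(B), converged = TRUE)
}

#' Classify pan-genome openness from the Heaps exponent
#'
#' Open exactly when B lies strictly inside (0, 1): the fitted pan-genome
#' size then grows without bound as genomes are added. B <= 0 or B >= 1
#' (including the boundaries) is closed.
#'
#' @param B the fitted Heaps exponent; must be finite.
#' @return \code{"open"} or \code{"closed"}.
#' @examples
#' classifyOpenness(0.48)   # "open"
#' classifyOpenness(1.2)    # "closed"
#' @export
classifyOpenness <- function(B) {
    if (!is.finite(B)) .stop_input("B must be finite")
    if (B > 0 && B < 1) "open" else "closed"
}

#' Fit the exponential model to the core-genome curve
#'
#' Nonlinear least squares of \code{y = A * exp(B * x) + C} on the
#' core-curve medians with multi-start initialization, mirroring
#' [fitHeaps()]. A non-increasing fitted curve over the observed range
#' corresponds to \code{A * B <= 0}. A constant curve short-circuits to
#' A = 0, C = y.
#'
#' @param curve a [PanCurves-class] (its core component is used) or a
#'   data.frame with columns \code{x} and \code{y_median}.
#' @return a [CoreFit-class].
#' @examples
#' x <- 1:10
#' fitCoreExponential(data.frame(x = x, y_median = 500 * exp(-0.3 * x) + 3000))
#' @export
fitCoreExponential <- function(curve) {
    xy <- .curve_xy(curve, "core")
    x <- xy$x; y <- xy$y
    if (length(x) < 4L) .stop_input("need at least 4 curve points")
    if (any(diff(x) <= 0)) .stop_input("x must be strictly increasing")
    if (diff(range(y)) < .Machine$double.eps * max(1, abs(y[1]))) {
        return(.make_fit("CoreFit", A = 0, B = 0, C = y[1], rss = 0,
                         converged = FALSE))
    }
    d <- max(y) - min(y)
    starts <- c(lapply(c(-0.1, -0.3, -0.7),
                       function(b) list(A = d, B = b, C = min(y))),
                list(list(A = -d, B = -0.3, C = max(y)),
                     list(A = d, B = 0.1, C = min(y))))
    fit <- .multi_start_fit(x, y, y ~ A * exp(B * x) + C, starts)
    .make_fit("CoreFit", A = unname(fit$coef["A"]),
              B = unname(fit$coef["B"]), C = unname(fit$coef["C"]),
              rss = fit$rss, converged = TRUE)
}

#' Expected number of new genes contributed by the next genome
#'
#' First difference of the fitted Heaps model:
#' \code{A * ((n+1)^B - n^B)}, the predicted growth of the pan-genome when
#' the (n+1)-th genome is added to a panel of n.
#'
#' @param fit a [HeapsFit-class].
#' @param n current number of genomes (>= 1).
#' @return expected new-gene count.
#' @examples
#' newGenesAtNext(heapsFit(624.45, 0.48, 3033.86), 17)
#' @export
newGenesAtNext <- function(fit, n) {
    if (n < 1) .stop_input("n must be >= 1")
    fit@A * ((n + 1)^fit@B - n^fit@B)
}

#' Plot pan- and core-genome curves
#'
#' Base-graphics plot of the per-ordering pan (blue) and core (green)
#' values with the medians connected, the conventional presentation of
#' pan-genome rarefaction.
#'
#' @param curves a [PanCurves-class].
#' @param ... passed to \code{plot}.
#' @importFrom graphics lines matpoints legend
#' @importFrom grDevices adjustcolor
#' @export
plotPanCurves <- function(curves, ...) {
    n <- nrow(curves@pan)
    ylim <- range(curves@samples$pan, curves@samples$core)
    plot(NA, xlim = c(1, n), ylim = ylim, xlab = "number of genomes",
         ylab = "gene families", ...)
    matpoints(seq_len(n), t(curves@samples$pan), pch = 16, cex = 0.4,
              col = grDevices::adjustcolor("steelblue", 0.3))
    matpoints(seq_len(n), t(curves@samples$core), pch = 16, cex = 0.4,
              col = grDevices::adjustcolor("seagreen", 0.3))
    lines(curves@pan$x, curves@pan$y_median, col = "steelblue", lwd = 2)
    lines(curves@core$x, curves@core$y_median, col = "seagreen", lwd = 2)
    legend("topleft", c("pan", "core"), col = c("steelblue", "seagreen"),
           lwd = 2, bty = "n")
    invisible(NULL)
}
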