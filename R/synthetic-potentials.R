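#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Construct an analytic potential surface
#'
#' Ground-truth 2D surfaces for validating the landscape pipeline:
#' \itemize{
#'   \item \code{harmonic}: V = kappa (x^2 + y^2) / 2.
#'   \item \code{double_well}: V = h ((x/a)^2 - 1)^2 + kappa y^2 / 2
#'     + tilt * x. Minima near (+/- a, 0); for tilt = 0 the saddle at x = 0
#'     gives the closed-form barrier deltaF = h.
#'   \item \code{channel}: the double well with its barrier top replaced by a
#'     flat plateau of length L at constant V = h (V = h ((s/a)^2 - 1)^2
#'     + kappa y^2 / 2 with s = sign(x) max(|x| - L/2, 0)). Same barrier
#'     height, analytically flat top — the controllable analogue of an
#'     extended, "malleable" transition state.
#' }
#'
#' @param kind "harmonic", "double_well" or "channel".
#' @param kappa harmonic stiffness, kcal/mol/Angstrom^2 (default 1).
#' @param h barrier height, kcal/mol (double_well/channel).
#' @param a half well separation, Angstrom (double_well/channel).
#' @param L plateau length, Angstrom (channel only).
#' @param tilt linear bias along x, kcal/mol/Angstrom (double_well only,
#'   default 0; lets the two wells carry unequal Boltzmann weight).
#' @return a \linkS4class{PotentialSpec}.
#' @examples
#' dw <- potentialSpec("double_well", h = 3, a = 1)
#' analyticBarrier(dw)
#' @export
potentialSpec <- function(kind = c("harmonic", "double_well", "channel"),
                          kappa = 1, h = NULL, a = NULL, L = NULL,
                          tilt = 0) {
  kind <- match.arg(kind)
  kappa <- .assertPositive(kappa, "kappa")
  if (kind == "harmonic") {
    pars <- list(kappa = kappa)
    barrier <- 0
  } else {
    h <- .assertPositive(h, "h")
    a <- .assertPositive(a, "a")
    pars <- list(kappa = kappa, h = h, a = a)
    if (kind == "channel") {
      pars$L <- .assertPositive(L, "L")
    } else {
      pars$tilt <- as.numeric(tilt)
    }
    barrier <- h
  }
  new("PotentialSpec", kind = kind, parameters = pars,
      analyticBarrier = barrier)
}

#' Evaluate a potential surface
#'
#' @param spec a \linkS4class{PotentialSpec}.
#' @param x,y coordinates (vectorized).
#' @return \code{potentialEnergy}: V(x, y) in kcal/mol.
#'   \code{potentialGradient}: a two-column matrix (dV/dx, dV/dy).
#' @export
potentialEnergy <- function(spec, x, y) {
  p <- spec@parameters
  switch(spec@kind,
    harmonic = 0.5 * p$kappa * (x^2 + y^2),
    double_well = p$h * ((x / p$a)^2 - 1)^2 + 0.5 * p$kappa * y^2 +
      (if (is.null(p$tilt)) 0 else p$tilt) * x,
    channel = {
      s <- sign(x) * pmax(abs(x) - p$L / 2, 0)
      p$h * ((s / p$a)^2 - 1)^2 + 0.5 * p$kappa * y^2
    }
  )
}

#' @rdname potentialEnergy
#' @export
potentialGradient <- function(spec, x, y) {
  p <- spec@parameters
  g <- switch(spec@kind,
    harmonic = cbind(p$kappa * x, p$kappa * y),
    double_well = {
      tilt <- if (is.null(p$tilt)) 0 else p$tilt
      cbind(4 * p$h * x * ((x / p$a)^2 - 1) / p$a^2 + tilt, p$kappa * y)
    },
    channel = {
      s <- sign(x) * pmax(abs(x) - p$L / 2, 0)
      cbind(4 * p$h * s * ((s / p$a)^2 - 1) / p$a^2, p$kappa * y)
    }
  )
  colnames(g) <- c("dx", "dy")
  g
}

#' Overdamped Langevin (Brownian) sampling of a potential surface
#'
#' Euler-Maruyama integration of the overdamped Langevin equation
#' x <- x - (dt / gamma) grad V + sqrt(2 kT dt / gamma) xi with standard
#' normal xi, one independent noise stream per call seeded explicitly.
#' At long times the samples follow the Boltzmann distribution
#' exp(-V / kT), which is what makes the sampler a ground-truth generator
#' for the statistical free-energy landscape.
#'
#' @param spec a \linkS4class{PotentialSpec}.
#' @param kT thermal energy, kcal/mol.
#' @param dt time step (the stability limit is roughly
#'   dt < gamma / max |V''|; a divergence aborts with an error naming dt).
#' @param nSteps number of steps; the returned series has nSteps + 1 rows.
#' @param friction gamma, the friction coefficient (default 1).
#' @param seed integer seed for the noise stream.
#' @param init length-2 starting point; default the left/lower minimum of
#'   the surface.
#' @return numeric (nSteps + 1) x 2 matrix of sampled points.
#' @examples
#' s <- brownianSample(potentialSpec("harmonic", kappa = 1), kT = 1,
#'                     dt = 0.01, nSteps = 1000, seed = 1)
#' dim(s)
#' @export
brownianSample <- function(spec, kT, dt, nSteps, friction = 1, seed = 1L,
                           init = NULL) {
  stopifnot(is(spec, "PotentialSpec"))
  if (length(kT) != 1L || !is.finite(kT) || kT < 0) {
    stop("kT must be a single non-negative number") # kT = 0 is the
  } # deterministic steepest-descent limit, useful as a sanity check
  dt <- .assertPositive(dt, "dt")
  nSteps <- .assertCount(nSteps, "nSteps")
  friction <- .assertPositive(friction, "friction")
  p <- spec@parameters
  if (is.null(init)) {
    init <- switch(spec@kind,
      harmonic = c(0, 0),
      double_well = c(-p$a, 0),
      channel = c(-(p$L / 2 + p$a), 0)
    )
  }
  if (any(!is.finite(potentialGradient(spec, init[1L], init[2L])))) {
    stop("potential gradient not finite at the initial point")
  }
  mob <- dt / friction
  sdNoise <- sqrt(2 * kT * dt / friction)
  out <- matrix(NA_real_, nSteps + 1L, 2L)
  out[1L, ] <- init
  bound <- 1e6
  .withSeed(seed, {
    noise <- matrix(stats::rnorm(2L * nSteps, sd = sdNoise), ncol = 2L)
    x <- init[1L]
    y <- init[2L]
    kind <- spec@kind
    kappa <- p$kappa
    if (kind == "harmonic") {
      for (i in seq_len(nSteps)) {
        x <- x - mob * kappa * x + noise[i, 1L]
        y <- y - mob * kappa * y + noise[i, 2L]
        out[i + 1L, 1L] <- x
        out[i + 1L, 2L] <- y
        if (abs(x) > bound || abs(y) > bound) {
          stop("sampler diverged; dt = ", dt, " is likely too large")
        }
      }
    } else if (kind == "double_well") {
      h <- p$h
      a2 <- p$a^2
      tilt <- if (is.null(p$tilt)) 0 else p$tilt
      for (i in seq_len(nSteps)) {
        gx <- 4 * h * x * (x * x / a2 - 1) / a2 + tilt
        x <- x - mob * gx + noise[i, 1L]
        y <- y - mob * kappa * y + noise[i, 2L]
        out[i + 1L, 1L] <- x
        out[i + 1L, 2L] <- y
        if (abs(x) > bound || abs(y) > bound) {
          stop("sampler diverged; dt = ", dt, " is likely too large")
        }
      }
    } else {
      h <- p$h
      a2 <- p$a^2
      halfL <- p$L / 2
      for (i in seq_len(nSteps)) {
        s <- if (x > halfL) x - halfL else if (x < -halfL) x + halfL else 0
        gx <- 4 * h * s * (s * s / a2 - 1) / a2
        x <- x - mob * gx + noise[i, 1L]
        y <- y - mob * kappa * y + noise[i, 2L]
        out[i + 1L, 1L] <- x
        out[i + 1L, 2L] <- y
        if (abs(x) > bound || abs(y) > bound) {
          stop("sampler diverged; dt = ", dt, " is likely too large")
        }
      }
    }
  })
  colnames(out) <- c("x", "y")
  out
}
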