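# Gas constant in kcal/(mol K); all energies in the package are kcal/mol,
# all coordinates Angstrom, all times ns.
.RGAS <- 1.9872e-3

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Every stochastic generator in the package
# funnels through this so that a (seed, parameters) pair is bit-reproducible
# and never perturbs the user's global stream.
.withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

.assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x)) {
    stop("'", name, "' must be a single integer >= ", min, call. = FALSE)
  }
  as.integer(x)
}

.assertPositive <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("'", name, "' must be a single positive number", call. = FALSE)
  }
  as.numeric(x)
}

# Standard atomic masses (amu) for the elements PDB files typically carry.
.ELEMENT_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305
)

.massFromElement <- function(elesy) {
  key <- toupper(trimws(elesy))
  m <- .ELEMENT_MASSES[key]
  m[is.na(m)] <- 12.011
  unname(m)
}
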