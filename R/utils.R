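# internal helpers shared across modules

# evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb
# user-level reproducibility
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# largest |z| representable through the log-tail quantile transform
.Z_CAP <- 38

# two-sided t -> z, exact in the far tails via log tail probabilities
t_to_z <- function(tval, dof, cap = .Z_CAP) {
  lp <- stats::pt(abs(tval), df = dof, lower.tail = FALSE, log.p = TRUE)
  z <- -stats::qnorm(lp, log.p = TRUE)
  z <- pmin(z, cap) * sign(tval)
  z[!is.finite(tval) & is.na(tval)] <- NA_real_
  z
}

# one-sided F -> z through the upper tail; small F maps to z <= 0
f_to_z <- function(fval, df1, df2, cap = .Z_CAP) {
  lp <- stats::pf(fval, df1, df2, lower.tail = FALSE, log.p = TRUE)
  z <- -stats::qnorm(lp, log.p = TRUE)
  pmax(pmin(z, cap), -cap)
}

.is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 0 && abs(x - round(x)) < 1e-9

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
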