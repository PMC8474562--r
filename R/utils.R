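#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. Keeps multi-start optimizers deterministic
# without clobbering user-level reproducibility.
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a base seed and a stage label; keeps every
# pipeline stage independently reproducible and below .Machine$integer.max.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stopf("'%s' must be finite and strictly positive", name)
  }
  invisible(x)
}

#' @importFrom stats approx coef complete.cases cor median optim p.adjust
#' @importFrom stats pt qt rbinom rgamma rlnorm rnorm runif sd setNames var
#' @importFrom stats glm.fit Gamma dgamma
#' @importFrom utils read.csv write.csv modifyList
NULL
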