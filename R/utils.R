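# Internal helpers shared across modules.

# Coerce expression input to a plain genes x samples numeric matrix.
# Accepts a matrix with dimnames or a SummarizedExperiment (first assay).
.asExprMatrix <- function(x, arg = "x") {
  if (methods::is(x, "SummarizedExperiment")) {
    x <- SummarizedExperiment::assay(x, 1L)
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(arg, " must be a numeric genes x samples matrix ",
         "or a SummarizedExperiment")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(arg, " must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop(arg, " has duplicated gene ids; collapse them first ",
         "(see readExpression)")
  if (anyNA(x)) stop(arg, " contains missing values")
  x
}

# Deterministic per-operation seed derived from a global seed and an
# operation name, so adding operations never perturbs earlier RNG streams.
# Kept strictly below 2^31.
.opSeed <- function(seed, op) {
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Run code under a local RNG stream without disturbing the caller's RNG.
.withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# log(sigmoid(z)) computed stably for large |z|.
.logSigmoid <- function(z) ifelse(z >= 0, -log1p(exp(-z)), z - log1p(exp(z)))
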