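# Internal helpers shared across modules.

# Signal a classed condition. `class` is one of "nasovol_input_error"
# (bad user input / precondition violation) or "nasovol_computation_error"
# (a well-formed request with no valid answer). Both inherit "nasovol_error".
nv_stop <- function(msg, class = "nasovol_input_error", data = list()) {
  cond <- errorCondition(msg, class = c(class, "nasovol_error"), call = sys.call(-1))
  for (nm in names(data)) cond[[nm]] <- data[[nm]]
  stop(cond)
}

nv_warn <- function(msg) {
  warning(warningCondition(msg, class = "nasovol_warning"), call. = FALSE)
}

is_num3 <- function(x) is.numeric(x) && length(x) == 3L && all(is.finite(x))

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# md5 of an R object via its serialization (provenance hashes).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}
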