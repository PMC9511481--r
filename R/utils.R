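# Internal helpers: seeding, pipeline-stage bookkeeping, formatting.

MOD31 <- 2147483647

# Counter-based seed splitting: mixes the master seed with integer counters by
# iterated Lehmer steps (48271 * h stays below 2^53, so the arithmetic is
# exact in doubles). Wells keyed by structural counters get stable streams:
# adding wells or experiments never perturbs the streams of existing ones.
mix_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% MOD31
  for (k in c(...)) {
    h <- (h * 48271 + (as.numeric(k) %% MOD31)) %% MOD31
  }
  as.integer(h %% (MOD31 - 1)) + 1L
}

# Run expr with a local RNG state so callers' streams are untouched.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Processing-stage bookkeeping. The AUC pipeline has a fixed order
# (correct -> auc -> subtract -> normalize); each step records the stage it
# produced and checks the stage it requires.
pipeline_stage <- function(x) attr(x, "ligandbias_stage") %||% "raw"

set_stage <- function(x, stage) {
  attr(x, "ligandbias_stage") <- stage
  x
}

require_stage <- function(x, allowed, op) {
  st <- pipeline_stage(x)
  if (!st %in% allowed) {
    stop(sprintf(
      "%s() expects input at stage %s but received stage '%s'; the processing order is corrected -> auc -> solvent_subtracted -> normalized",
      op, paste(sprintf("'%s'", allowed), collapse = " or "), st
    ), call. = FALSE)
  }
  invisible(x)
}

# Format a positive number to 3 significant figures the way report tables
# print nanomolar potencies (no scientific notation below 10000).
fmt_sig3 <- function(x) {
  ifelse(is.na(x), "n.d.", vapply(x, function(v) {
    if (is.na(v)) return("n.d.")
    format(signif(v, 3), scientific = FALSE, trim = TRUE, big.mark = "")
  }, character(1)))
}

fmt_ci <- function(est, lo, hi) {
  ifelse(is.na(est), "n.d.",
         ifelse(is.na(lo) | is.na(hi),
                paste0(fmt_sig3(est), " [n.d.]"),
                paste0(fmt_sig3(est), " [", fmt_sig3(lo), "-", fmt_sig3(hi), "]")))
}

fmt_beta <- function(x) ifelse(is.na(x), "n.d.", sprintf("%.3f", x))
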